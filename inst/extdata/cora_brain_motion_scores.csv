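case,adapt,kth_original,kth_fsi,kth_detailed
C288-T3,0.588,0.423,0.540,0.538
C380-T1,0.694,0.560,NA,0.749
C380-T2,0.549,0.416,NA,0.623
C380-T3,0.650,0.503,NA,0.677
C380-T4,0.658,0.551,0.646,0.721
C380-T6,0.625,0.511,NA,0.702
C393-T3,0.555,0.500,NA,0.573
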