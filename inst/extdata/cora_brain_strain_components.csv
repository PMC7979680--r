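cluster,metric,V,G,P,score
C288-T3 C1,principal,0.947,0.361,0.828,0.712
C380-T1 C1,principal,0.977,0.924,0.721,0.874
C380-T2 C1,principal,0.986,0.378,0.935,0.766
C380-T3 C1,principal,0.982,0.293,0.999,0.758
C380-T4 C1,principal,0.979,0.249,0.935,0.721
C380-T6 C1,principal,0.977,0.235,0.828,0.680
C393-T3 C1,principal,0.934,0.561,0.999,0.832
C288-T3 C1,shear,0.956,0.426,0.935,0.772
C380-T1 C1,shear,0.975,0.940,0.721,0.879
C380-T2 C1,shear,0.983,0.542,0.935,0.820
C380-T3 C1,shear,0.980,0.396,0.935,0.770
C380-T4 C1,shear,0.979,0.317,0.935,0.744
C380-T6 C1,shear,0.981,0.308,0.721,0.670
C393-T3 C1,shear,0.925,0.462,0.935,0.774
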