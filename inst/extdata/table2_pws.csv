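case,n,baseline_maxQ_r,baseline_maxQ_p,baseline_minQ_r,baseline_minQ_p,followup_maxQ_r,followup_maxQ_p,followup_minQ_r,followup_minQ_p
C1,400,-0.060,0.232,-0.059,0.243,-0.301,< .001,-0.299,< .001
C2,400,0.192,< .001,0.192,< .001,-0.209,< .001,-0.209,< .001
C3,900,0.019,0.564,0.022,0.505,-0.440,< .001,-0.437,< .001
C4,400,0.467,< .001,0.469,< .001,-0.079,0.116,-0.085,0.091
C5,800,0.270,< .001,0.260,< .001,-0.108,0.002,-0.129,< .001
C6,800,-0.039,0.274,-0.023,0.508,-0.279,< .001,-0.275,< .001
C7,800,0.133,< .001,0.145,< .001,-0.179,< .001,-0.166,< .001
C8,800,0.267,< .001,0.263,< .001,-0.133,< .001,-0.141,< .001
C9,600,0.457,< .001,0.457,< .001,0.208,< .001,0.208,< .001
C10,600,-0.297,< .001,-0.297,< .001,-0.622,< .001,-0.622,< .001
C11,700,-0.048,0.208,-0.043,0.252,-0.325,< .001,-0.329,< .001
C12,700,-0.024,0.530,-0.015,0.695,-0.228,< .001,-0.218,< .001
C13,600,-0.119,0.004,-0.120,0.003,-0.229,< .001,-0.242,< .001
C14,1000,-0.098,0.002,-0.097,0.002,-0.341,< .001,-0.342,< .001
C15,1000,0.235,< .001,0.240,< .001,-0.101,0.001,-0.100,0.002
C16,900,-0.037,0.269,-0.037,0.262,-0.302,< .001,-0.307,< .001
C17,800,-0.125,< .001,-0.121,< .001,-0.386,< .001,-0.383,< .001
C18,800,0.030,0.397,0.030,0.396,-0.368,< .001,-0.369,< .001
C19,800,-0.017,0.632,-0.016,0.649,-0.228,< .001,-0.228,< .001
C20,800,0.492,< .001,0.491,< .001,0.253,< .001,0.252,< .001
C21,900,0.097,0.004,0.094,0.005,-0.080,0.016,-0.081,0.015
C22,900,-0.135,< .001,-0.135,< .001,-0.241,< .001,-0.241,< .001
C23,700,0.408,< .001,0.412,< .001,-0.144,< .001,-0.143,< .001
C24,800,0.242,< .001,0.242,< .001,-0.402,< .001,-0.403,< .001
C25,800,0.227,< .001,0.226,< .001,-0.374,< .001,-0.375,< .001
C26,700,0.107,0.005,0.107,0.005,-0.221,< .001,-0.220,< .001
C27,700,0.024,0.531,0.019,0.609,-0.416,< .001,-0.415,< .001
C28,900,0.470,< .001,0.470,< .001,-0.011,0.741,-0.014,0.673
C29,900,0.080,0.017,0.087,0.009,0.013,0.694,0.016,0.639
C30,800,0.110,0.002,0.112,0.002,-0.052,0.140,-0.051,0.152
C31,800,0.127,< .001,0.125,< .001,-0.149,< .001,-0.154,< .001
C32,800,0.119,0.001,0.117,< .001,-0.158,< .001,-0.161,< .001
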