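case,n,baseline_maxQ_r,baseline_maxQ_p,baseline_minQ_r,baseline_minQ_p,followup_maxQ_r,followup_maxQ_p,followup_minQ_r,followup_minQ_p
C1,400,0.015,0.761,0.025,0.619,0.125,0.013,0.130,0.009
C2,400,-0.108,0.032,-0.110,0.027,0.058,0.247,0.057,0.256
C3,900,0.338,< .001,0.337,< .001,0.401,< .001,0.403,< .000
C4,400,-0.450,< .001,-0.460,< .001,-0.144,0.004,-0.173,0.001
C5,800,0.170,< .001,0.181,< .001,0.432,< .000,0.439,< .000
C6,800,-0.379,< .001,-0.384,< .001,0.123,0.001,0.114,0.001
C7,800,0.117,0.001,0.108,0.002,0.125,< .001,0.126,< .001
C8,800,-0.088,0.013,-0.090,0.011,0.183,< .001,0.181,< .001
C9,600,-0.305,< .001,-0.300,< .001,-0.288,< .001,-0.293,< .001
C10,600,0.392,< .001,0.391,< .001,0.348,< .001,0.352,< .001
C11,700,-0.313,< .001,-0.307,< .001,-0.311,< .001,-0.312,< .001
C12,700,0.005,0.887,0.008,0.834,-0.077,0.043,-0.072,0.056
C13,600,-0.117,0.004,-0.110,0.007,-0.027,0.513,-0.013,0.745
C14,1000,0.188,< .001,0.193,< .001,0.337,< .001,0.340,< .001
C15,1000,0.108,< .001,0.102,0.001,0.257,< .001,0.252,< .001
C16,900,0.007,0.845,-0.010,0.760,-0.146,< .001,0.310,< .001
C17,800,0.188,< .001,-0.199,< .001,0.273,< .001,0.288,< .001
C18,800,0.056,0.116,0.054,0.128,0.154,< .001,0.159,< .001
C19,800,-0.032,0.361,-0.025,0.484,0.274,< .001,0.283,< .001
C20,800,-0.587,< .001,-0.588,< .001,-0.468,< .001,-0.463,< .001
C21,900,0.135,< .001,0.134,< .001,0.139,< .001,0.137,< .001
C22,900,-0.036,0.282,-0.053,0.111,0.006,0.858,0.002,0.947
C23,700,-0.051,0.182,-0.041,0.281,0.263,< .001,0.272,< .001
C24,800,0.028,0.436,0.021,0.548,0.082,0.020,0.081,0.022
C25,800,-0.021,0.547,-0.029,0.421,0.193,< .001,0.203,< .001
C26,700,0.054,0.150,0.058,0.128,0.153,< .001,0.162,< .001
C27,700,-0.382,< .001,-0.389,< .001,-0.044,0.246,-0.037,0.329
C28,900,-0.369,< .001,-0.373,< .001,-0.223,< .001,-0.225,< .001
C29,900,0.207,< .001,0.215,< .001,0.207,< .001,0.205,< .001
C30,800,0.332,< .001,0.336,< .001,0.361,< .001,0.364,< .001
C31,800,-0.420,< .001,-0.418,< .001,-0.357,< .001,-0.354,< .001
C32,800,-0.489,< .001,-0.498,< .001,-0.170,< .001,-0.175,< .001
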