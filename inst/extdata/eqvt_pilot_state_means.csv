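site,arm,state,mean,sd
china,standard,11145,0.32,0.60
china,standard,11221,0.49,0.53
china,standard,12112,0.50,0.50
china,standard,21111,0.50,0.56
china,standard,33133,0.32,0.59
china,standard,44113,0.36,0.54
china,standard,52221,0.38,0.60
china,standard,52324,0.22,0.66
china,standard,53555,0.19,0.64
china,standard,55523,0.20,0.63
china,experimental,11145,0.41,0.42
china,experimental,11221,0.59,0.41
china,experimental,12112,0.53,0.47
china,experimental,21111,0.60,0.42
china,experimental,33133,0.43,0.46
china,experimental,44113,0.34,0.46
china,experimental,52221,0.47,0.46
china,experimental,52324,0.37,0.43
china,experimental,53555,0.34,0.46
china,experimental,55523,0.24,0.51
singapore,standard,11145,0.14,0.72
singapore,standard,11221,0.49,0.60
singapore,standard,12112,0.57,0.58
singapore,standard,21111,0.56,0.63
singapore,standard,33133,0.32,0.66
singapore,standard,44113,0.02,0.81
singapore,standard,52221,0.08,0.74
singapore,standard,52324,0.06,0.74
singapore,standard,53555,-0.14,0.84
singapore,standard,55523,-0.13,0.82
singapore,experimental,11145,0.04,0.75
singapore,experimental,11221,0.60,0.49
singapore,experimental,12112,0.46,0.71
singapore,experimental,21111,0.68,0.48
singapore,experimental,33133,0.36,0.70
singapore,experimental,44113,0.15,0.74
singapore,experimental,52221,0.26,0.69
singapore,experimental,52324,0.05,0.79
singapore,experimental,53555,-0.11,0.74
singapore,experimental,55523,-0.21,0.81
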