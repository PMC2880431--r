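{
  "allele_frequency": 0.0006,
  "ages": [20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84],
  "hazard": {
    "carrier": {
      "ERneg": [0.00062078456613, 0.00062078456613, 0.00062078456613, 0.00062078456613, 0.00062078456613, 0.0011129891644, 0.0011129891644, 0.0011129891644, 0.0011129891644, 0.0011129891644, 0.0019703772735, 0.0019703772735, 0.0019703772735, 0.0019703772735, 0.0019703772735, 0.0034135372569, 0.0034135372569, 0.0034135372569, 0.0034135372569, 0.0034135372569, 0.005707923616, 0.005707923616, 0.005707923616, 0.005707923616, 0.005707923616, 0.009044119078, 0.009044119078, 0.009044119078, 0.009044119078, 0.009044119078, 0.0071014905007, 0.0071014905007, 0.0071014905007, 0.0071014905007, 0.0071014905007, 0.0095860094993, 0.0095860094993, 0.0095860094993, 0.0095860094993, 0.0095860094993, 0.011863969825, 0.011863969825, 0.011863969825, 0.011863969825, 0.011863969825, 0.013643274071, 0.013643274071, 0.013643274071, 0.013643274071, 0.013643274071, 0.014866946796, 0.014866946796, 0.014866946796, 0.014866946796, 0.014866946796, 0.015636632121, 0.015636632121, 0.015636632121, 0.015636632121, 0.015636632121, 0.016093905779, 0.016093905779, 0.016093905779, 0.016093905779, 0.016093905779],
      "ERpos": [0.00020692818871, 0.00020692818871, 0.00020692818871, 0.00020692818871, 0.00020692818871, 0.00037099638812, 0.00037099638812, 0.00037099638812, 0.00037099638812, 0.00037099638812, 0.0006567924245, 0.0006567924245, 0.0006567924245, 0.0006567924245, 0.0006567924245, 0.0011378457523, 0.0011378457523, 0.0011378457523, 0.0011378457523, 0.0011378457523, 0.0019026412053, 0.0019026412053, 0.0019026412053, 0.0019026412053, 0.0019026412053, 0.0030147063593, 0.0030147063593, 0.0030147063593, 0.0030147063593, 0.0030147063593, 0.0023671635002, 0.0023671635002, 0.0023671635002, 0.0023671635002, 0.0023671635002, 0.0031953364998, 0.0031953364998, 0.0031953364998, 0.0031953364998, 0.0031953364998, 0.0039546566084, 0.0039546566084, 0.0039546566084, 0.0039546566084, 0.0039546566084, 0.0045477580238, 0.0045477580238, 0.0045477580238, 0.0045477580238, 0.0045477580238, 0.0049556489321, 0.0049556489321, 0.0049556489321, 0.0049556489321, 0.0049556489321, 0.0052122107069, 0.0052122107069, 0.0052122107069, 0.0052122107069, 0.0052122107069, 0.0053646352597, 0.0053646352597, 0.0053646352597, 0.0053646352597, 0.0053646352597]
    },
    "noncarrier": {
      "ERneg": [1.1036170065e-05, 1.1036170065e-05, 1.1036170065e-05, 1.1036170065e-05, 1.1036170065e-05, 1.9786474033e-05, 1.9786474033e-05, 1.9786474033e-05, 1.9786474033e-05, 1.9786474033e-05, 3.5028929307e-05, 3.5028929307e-05, 3.5028929307e-05, 3.5028929307e-05, 3.5028929307e-05, 6.068510679e-05, 6.068510679e-05, 6.068510679e-05, 6.068510679e-05, 6.068510679e-05, 0.00010147419762, 0.00010147419762, 0.00010147419762, 0.00010147419762, 0.00010147419762, 0.00016078433916, 0.00016078433916, 0.00016078433916, 0.00016078433916, 0.00016078433916, 0.00023671635002, 0.00023671635002, 0.00023671635002, 0.00023671635002, 0.00023671635002, 0.00031953364998, 0.00031953364998, 0.00031953364998, 0.00031953364998, 0.00031953364998, 0.00039546566084, 0.00039546566084, 0.00039546566084, 0.00039546566084, 0.00039546566084, 0.00045477580238, 0.00045477580238, 0.00045477580238, 0.00045477580238, 0.00045477580238, 0.00049556489321, 0.00049556489321, 0.00049556489321, 0.00049556489321, 0.00049556489321, 0.00052122107069, 0.00052122107069, 0.00052122107069, 0.00052122107069, 0.00052122107069, 0.00053646352597, 0.00053646352597, 0.00053646352597, 0.00053646352597, 0.00053646352597],
      "ERpos": [4.4144680258e-05, 4.4144680258e-05, 4.4144680258e-05, 4.4144680258e-05, 4.4144680258e-05, 7.9145896132e-05, 7.9145896132e-05, 7.9145896132e-05, 7.9145896132e-05, 7.9145896132e-05, 0.00014011571723, 0.00014011571723, 0.00014011571723, 0.00014011571723, 0.00014011571723, 0.00024274042716, 0.00024274042716, 0.00024274042716, 0.00024274042716, 0.00024274042716, 0.00040589679047, 0.00040589679047, 0.00040589679047, 0.00040589679047, 0.00040589679047, 0.00064313735666, 0.00064313735666, 0.00064313735666, 0.00064313735666, 0.00064313735666, 0.00094686540009, 0.00094686540009, 0.00094686540009, 0.00094686540009, 0.00094686540009, 0.0012781345999, 0.0012781345999, 0.0012781345999, 0.0012781345999, 0.0012781345999, 0.0015818626433, 0.0015818626433, 0.0015818626433, 0.0015818626433, 0.0015818626433, 0.0018191032095, 0.0018191032095, 0.0018191032095, 0.0018191032095, 0.0018191032095, 0.0019822595728, 0.0019822595728, 0.0019822595728, 0.0019822595728, 0.0019822595728, 0.0020848842828, 0.0020848842828, 0.0020848842828, 0.0020848842828, 0.0020848842828, 0.0021458541039, 0.0021458541039, 0.0021458541039, 0.0021458541039, 0.0021458541039]
    }
  }
}
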