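{
  "sigma_0": 1.2, "sigma_1": 3e-07, "sigma_2": 0.3, "sigma_3": 3e-07, "sigma_4": 0.3,
  "epsilon_0": 6.4e-10, "epsilon_1": 4.4e-11, "epsilon_2": 6.4e-10, "epsilon_3": 4.4e-11, "epsilon_4": 6.4e-10,
  "R": 10, "D": 5, "r": 3, "d": 5,
  "B0": 2, "f": 10, "C": 10
}
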