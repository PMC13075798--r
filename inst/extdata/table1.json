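{
  "kernels": {
    "AMPA": {
      "A": 3.25,
      "a": 100,
      "label": "AMPA"
    },
    "GABA_slow": {
      "A": -22,
      "a": 50,
      "label": "GABA_slow"
    },
    "GABA_fast": {
      "A": -30,
      "a": 220,
      "label": "GABA_fast"
    }
  },
  "sigmoid": {
    "v0": 6,
    "v0_P2": 1,
    "phi0": 2.5,
    "r": 0.56
  },
  "connectivity": {
    "C1": 108,
    "C2": 33.7,
    "C3": 1,
    "C4": 135,
    "C5": 33.75,
    "C6": 70,
    "C7": 550,
    "C8": 1,
    "C9": 200,
    "C10": 100,
    "C11": 80,
    "C12": 200,
    "C13": 30
  },
  "inputs": {
    "phi_e1": 0,
    "phi_e2": 0
  }
}
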