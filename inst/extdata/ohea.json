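{
  "n_qubits": 4,
  "initial_state": 0,
  "gates": [
    {
      "name": "X",
      "qubits": 2
    },
    {
      "name": "RY",
      "qubits": 4,
      "param_index": 1,
      "mult": 1
    },
    {
      "name": "CRY",
      "qubits": [4, 1],
      "param_index": 2,
      "mult": 1
    },
    {
      "name": "CRY",
      "qubits": [1, 3],
      "param_index": 3,
      "mult": 1
    },
    {
      "name": "CNOT",
      "qubits": [3, 2]
    },
    {
      "name": "CRY",
      "qubits": [2, 1],
      "param_index": 4,
      "mult": 1
    },
    {
      "name": "CRY",
      "qubits": [1, 2],
      "param_index": 5,
      "mult": 1
    },
    {
      "name": "CNOT",
      "qubits": [4, 3]
    }
  ],
  "meta": {
    "ansatz": "ohea",
    "sector": "open-shell (3e,3o), 2a/1b",
    "note": "synthesized greedily on the packaged allyl-radical fixture; depth 6, 5 parameters"
  }
}
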