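{
  "n_qubits": 4,
  "initial_state": 0,
  "gates": [
    {
      "name": "X",
      "qubits": 1
    },
    {
      "name": "RY",
      "qubits": 2,
      "param_index": 1,
      "mult": 1
    },
    {
      "name": "CNOT",
      "qubits": [2, 4]
    },
    {
      "name": "CRY",
      "qubits": [2, 1],
      "param_index": 2,
      "mult": 1
    },
    {
      "name": "CNOT",
      "qubits": [1, 3]
    }
  ],
  "meta": {
    "ansatz": "chea",
    "sector": "closed-shell (4e,3o), 2a/2b",
    "note": "synthesized greedily on the packaged allyl-anion fixture; depth 4, 2 parameters"
  }
}
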