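{
  "basis": "model",
  "provenance": "synthetic example reference set (exact-diagonalization IPs of the shipped model Hamiltonians; not experimental or coupled-cluster data)",
  "entries": {
    "hubbard-dimer(t=1,U=2)": 6.42373691605598,
    "hubbard-dimer(t=1,U=1)": 15.2806304868621,
    "hubbard-dimer(t=1,U=0.5)": 20.8320695934303
  }
}
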