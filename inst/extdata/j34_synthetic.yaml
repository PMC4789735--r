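name: J34 (synthetic stand-in sequence)
arm_length: 17
strands:
  X: CTGATGCCGTAATGGCTCGATCGGTACCATGTTA
  R: TAACATGGTACCGATCGATTGCACCGGTAATCGC
  H: GCGATTACCGGTGCAATCTAGGCAATGCCATAGT
  B: ACTATGGCATTGCCTAGAGCCATTACGGCATCAG
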