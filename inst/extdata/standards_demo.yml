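standards:
- id: STD:01
  length: 500.0
  copies_added: 1.0e+08
  group: G1
- id: STD:02
  length: 577.0
  copies_added: 2.0309176e+08
  group: G1
- id: STD:03
  length: 654.0
  copies_added: 4.1246264e+08
  group: G1
- id: STD:04
  length: 731.0
  copies_added: 8.3767764e+08
  group: G1
- id: STD:05
  length: 808.0
  copies_added: 1.7012543e+09
  group: G2
- id: STD:06
  length: 885.0
  copies_added: 3.4551073e+09
  group: G2
- id: STD:07
  length: 962.0
  copies_added: 7.0170383e+09
  group: G2
- id: STD:08
  length: 1038.0
  copies_added: 1.4251027e+10
  group: G2
- id: STD:09
  length: 1115.0
  copies_added: 2.8942661e+10
  group: G3
- id: STD:10
  length: 1192.0
  copies_added: 5.8780161e+10
  group: G3
- id: STD:11
  length: 1269.0
  copies_added: 1.1937766e+11
  group: G3
- id: STD:12
  length: 1346.0
  copies_added: 2.424462e+11
  group: G4
- id: STD:13
  length: 1423.0
  copies_added: 4.9238826e+11
  group: G4
- id: STD:14
  length: 1500.0
  copies_added: 1.0e+12
  group: G4
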