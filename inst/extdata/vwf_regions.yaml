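# VWF mechanomodule segment definitions (author residue numbering).
regions:
- name: mechanomodule
  chain: '*'
  ranges:
  - [764, 1873]
  heavy_only: true
- name: d_d3
  chain: '*'
  ranges:
  - [764, 1237]
  heavy_only: true
- name: nfp
  chain: '*'
  ranges:
  - [1238, 1267]
  heavy_only: true
- name: naim
  chain: '*'
  ranges:
  - [1238, 1271]
  heavy_only: true
- name: naim_proximal
  chain: '*'
  ranges:
  - [1268, 1271]
  heavy_only: true
- name: a1_core
  chain: '*'
  ranges:
  - [1272, 1458]
  heavy_only: true
- name: align_anchor
  chain: '*'
  ranges:
  - [1290, 1430]
  heavy_only: true
- name: caim
  chain: '*'
  ranges:
  - [1459, 1493]
  heavy_only: true
- name: receptor
  chain: '*'
  ranges:
  - [1, 265]
  heavy_only: true
glycans: []
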