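# Seawall "simple tile": 40 x 40 cm concrete tile with square pits whose
# width, depth and spacing are all fixed, laid out on an ordered grid.
tile:
  width: 400.0
  length: 400.0
  thickness: 60.0
  units: mm
arrangement: ordered
buffer: 8.0
seed: 1
density: 25
abundances:
- 1.0
object_types:
- type_id: pit
  shape: square
  colour: '#4477AA'
  footprint:
    kind: fixed
    min: 32.0
    max: 32.0
  depth:
    kind: fixed
    min: 24.0
    max: 24.0
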