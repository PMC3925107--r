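# Seawall "complex tile": same tile, density and mean pit dimensions as the
# simple tile, but size and depth drawn from discrete lattices centred on
# the simple tile's fixed values, with randomised placement.
tile:
  width: 400.0
  length: 400.0
  thickness: 60.0
  units: mm
arrangement: random
buffer: 8.0
seed: 1
density: 25
abundances:
- 1.0
object_types:
- type_id: pit
  shape: square
  colour: '#EE6677'
  footprint:
    kind: discrete-uniform
    min: 8.0
    max: 56.0
    by: 8.0
  depth:
    kind: discrete-uniform
    min: 8.0
    max: 40.0
    by: 8.0
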