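# Rugged two-minimum fixture potential, version 1.
# Two deep wells (E, B) separated along x, plus two shallow intermediate
# wells displaced off the direct path that act as kinetic traps.
# Depths in kT, lengths in reduced units.
version: 1
kconf: 1.0
kT: 1.0
D: 1.0
wells:
  - name: E
    center: [-1.3, 0.0]
    depth: 7.0
    width: 0.50
  - name: B
    center: [1.3, 0.0]
    depth: 7.5
    width: 0.55
  - name: trap1
    center: [0.0, 0.7]
    depth: 4.5
    width: 0.35
  - name: trap2
    center: [0.15, -0.6]
    depth: 4.0
    width: 0.33
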