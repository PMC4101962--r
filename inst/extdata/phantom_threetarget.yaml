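# Synthetic three-target temporal-bone phantom (desk-scale study scene).
# A hollow hemispherical bone dome with capsule/sphere/torus-arc analogues
# of the at-risk structures, and targets at round-window-like (25 mm),
# internal-auditory-canal-like (40 mm) and petrous-apex-like (55 mm) depths
# below the outer surface.
seed: 1
spacing: [0.5, 0.5, 0.5]
bone_shell:
  outer_radius: 62
  thickness: 4
  center: [0, 0, 0]
obstacles:
  - name: facial_nerve
    kind: capsule
    a: [20, 7, 28]
    b: [26, 16, 44]
    radius: 1.5
    critical: true
  - name: chorda_tympani
    kind: capsule
    a: [17, 12, 30]
    b: [21, 18, 42]
    radius: 0.6
    critical: true
  - name: cochlea
    kind: sphere
    center: [9, 13, 35]
    radius: 3.5
    critical: true
  - name: ossicles
    kind: sphere
    center: [14, 15, 40]
    radius: 1.5
    critical: true
  - name: labyrinth
    kind: torus_arc
    center: [14, 4, 39]
    normal: [0.3, 0.88, 0.37]
    radius: 4
    tube_radius: 1.3
    angle_start: 0
    angle_end: 300
    critical: true
  - name: jugular_carotid
    kind: capsule
    a: [-1, -12, 4]
    b: [9, -4, 18]
    radius: 2.5
    critical: true
  - name: sigmoid_sinus
    kind: capsule
    a: [-16, 8, 12]
    b: [-8, 14, 40]
    radius: 3.0
    critical: true
  - name: dura
    kind: sphere
    center: [-18, 2, 30]
    radius: 6
    critical: true
targets:
  - name: RW
    point: [12.935, 11.087, 32.896]
    entry_seed: [21.674, 18.578, 55.124]
    noncritical: [cochlea, ossicles]
  - name: IAC
    point: [-4.419, 2.210, 21.440]
    entry_seed: [-12.453, 6.227, 60.419]
    noncritical: []
  - name: PA
    point: [0.703, -1.407, 6.823]
    entry_seed: [6.230, -12.459, 60.426]
    noncritical: []
planning:
  drill_radius: 0.5
  safety_distance: 1.0
  drill_inaccuracy: 0.5
  entry_region_radius: 8
selection:
  w_clearance: 1
  w_angle: 1
  m_cap: 40
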