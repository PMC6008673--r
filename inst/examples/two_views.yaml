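# One volume rendered from two perspectives by two renderer nodes.
nodes:
  - id: src
    kind: sphere_phantom
    params: {dims: [48, 48, 48], radius: 14, inside: 1, outside: 0}
  - id: view_front
    kind: volume_renderer
    params: {width: 96, height: 96, mode: solid, threshold: 0.5,
             eye: [24, -60, 24], target: [24, 24, 24]}
  - id: view_above
    kind: volume_renderer
    params: {width: 96, height: 96, mode: translucent, opacityScale: 1.5,
             eye: [80, 24, 90], target: [24, 24, 24]}
  - id: out_front
    kind: write_image
    params: {path: view_front.png}
  - id: out_above
    kind: write_image
    params: {path: view_above.png}
edges:
  - src.volume -> view_front.input
  - src.volume -> view_above.input
  - view_front.image -> out_front.input
  - view_above.image -> out_above.input
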