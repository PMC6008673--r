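# Skull-shell removal via the distance transform: voxels within two voxels
# of skull/skin material are suppressed, the rest is kept; the result is
# red/cyan stereo-rendered.
nodes:
  - id: ph
    kind: head_phantom
    params: {dims: [64, 64, 64], noiseSd: 0, seed: 1}
  - id: edt
    kind: distance_transform
    params: {threshold: 0.8}
  - id: keep
    kind: compute_snippet
    params:
      source: |
        param standoff = 2
        clamp(v - standoff, 0, 1)
  - id: stripped
    kind: elementwise
    params: {op: mul}
  - id: render
    kind: volume_renderer
    params: {width: 96, height: 96, mode: translucent, opacityScale: 2,
             step: 0.5, stereo: true, eyeSep: 6}
  - id: out_img
    kind: write_image
    params: {path: shell_removed_anaglyph.png}
  - id: out_vol
    kind: write_volume
    params: {path: shell_removed.vxvf}
edges:
  - ph.volume -> edt.input
  - edt.output -> keep.input
  - ph.volume -> stripped.a
  - keep.output -> stripped.b
  - stripped.output -> render.input
  - render.image -> out_img.input
  - stripped.output -> out_vol.input
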