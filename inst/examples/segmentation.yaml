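# Tissue segmentation on the synthetic head phantom:
# extract the skull/skin intensity band, smooth + threshold it into a mask,
# strip skull/skin from the volume with the mask, label the tissue classes
# with a per-voxel snippet, contrast-enhance the remainder, and extract a
# slice for display.
nodes:
  - id: ph
    kind: head_phantom
    params: {dims: [64, 64, 64], noiseSd: 0, seed: 1}
  - id: norm
    kind: rescale_intensity
  - id: skullband
    kind: threshold
    params: {t: 0.85}
  - id: smooth
    kind: gaussian_blur
    params: {sigma: 1}
  - id: mask
    kind: threshold
    params: {t: 0.5}
  - id: invmask
    kind: compute_snippet
    params: {source: "1 - v"}
  - id: stripped
    kind: elementwise
    params: {op: mul}
  - id: enhanced
    kind: compute_snippet
    params:
      source: |
        param exp = 1.5
        pow(v, exp)
  - id: labels
    kind: compute_snippet
    params:
      source: |
        clamp((v - 0.15)*1000000, 0, 1) + clamp((v - 0.45)*1000000, 0, 1) + clamp((v - 0.85)*1000000, 0, 1)
  - id: slice
    kind: extract_slice
    params: {axis: 3, index: 32}
  - id: out_labels
    kind: write_volume
    params: {path: labels.vxvf}
  - id: out_mask
    kind: write_volume
    params: {path: mask.vxvf}
  - id: out_slice
    kind: write_image
    params: {path: segmented_slice.png}
edges:
  - ph.volume -> norm.input
  - norm.output -> skullband.input
  - skullband.output -> smooth.input
  - smooth.output -> mask.input
  - mask.output -> invmask.input
  - norm.output -> stripped.a
  - invmask.output -> stripped.b
  - stripped.output -> enhanced.input
  - norm.output -> labels.input
  - enhanced.output -> slice.input
  - labels.output -> out_labels.input
  - mask.output -> out_mask.input
  - slice.image -> out_slice.input
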