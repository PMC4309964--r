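# Example pipeline configuration. Kernel sizes and thresholds are
# deliberately user-designated: tune them to your images.
input:
  path: movie.tif        # multi-page grayscale TIFF
  pixel_size_um: 0.2
  dt_s: 60
  mode: 2d               # or 3d (then set dz_um and z_count)
  # dz_um: 0.5
  # z_count: 7
  # page_order: tz       # t-major pages (t0z0, t0z1, ...); zt flips

preprocess:
  gaussian_sigma_px: 1.0
  lowpass_kernel_px: 51  # must be large relative to adhesion diameter

segment:
  local_kernel_px: 15    # comparable to the adhesion diameter in px
  local_offset: 0.0      # raise to reject noise (corrected-image units)
  cell_threshold: otsu   # or a number; 0 keeps the whole field
  min_area_um2: 1.0
  connectivity: 8

track:
  max_link_um: 2.0
  z_link_radius_um: 1.0
  min_track_len: 3

kinetics:
  min_run: 5
  intensity: raw         # raw preserves exponential amplitude changes
  lifetime_bin_min: 2
  size_bin_um2: 2

output:
  dir: adhesion_out
  write_overlays: false
  overlay_ids: true
  intensity: corrected   # intensity column of tracks.csv

seed: 1
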