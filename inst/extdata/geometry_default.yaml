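# Default channel geometry for the synthetic double-membrane system.
# Axial coordinates are relative to the selectivity-filter centre;
# +z points extracellular.  All intervals are half-open [lo, hi).
axis: [0.0, 0.0, 1.0]
axis_origin: [30.0, 30.0, 120.0]
region_bounds:
  intracellular_bulk: [-55.0, -18.0]
  cavity: [-18.0, -6.0]
  sf: [-6.0, 6.0]
  vestibule: [6.0, 12.0]
  extracellular_bulk: [12.0, 40.0]
sf_radius: 4.5
side_portal_radius_min: 5.5     # portal annulus spans (4.5, 10] A radially
site_planes:
  S4: -3.5
  B34: -2.0                     # T63 carbonyl-oxygen plane
  S3: -0.5
  B23: 1.0                      # V64 carbonyl-oxygen plane
  S2: 2.5
  S1: 4.0
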