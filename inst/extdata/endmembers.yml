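# Endmember reflectance spectra (band reflectance, dimensionless [0,1])
# for the synthetic field generator's two-endmember canopy mixing model.
# Bands: blue 475 nm, green 560 nm, red 668 nm, red-edge 717 nm, NIR 842 nm.
#
# healthy_canopy: dense, high-chlorophyll corn canopy -- deep red absorption,
#   strong red-edge shoulder and NIR plateau (NDVIre ~ 0.72).
# stressed_canopy: chlorotic/stressed canopy -- raised red, depressed
#   red-edge and NIR (NDVIre ~ 0.38).
# bare_soil: dry dark clay soil -- monotonically rising, flat red edge
#   (NDVIre ~ 0.02), so red-edge NDVI separates canopy from soil bimodally.
healthy_canopy:
  blue: 0.028
  green: 0.075
  red: 0.042
  rededge: 0.260
  nir: 0.520
stressed_canopy:
  blue: 0.045
  green: 0.090
  red: 0.085
  rededge: 0.190
  nir: 0.340
bare_soil:
  blue: 0.100
  green: 0.160
  red: 0.235
  rededge: 0.245
  nir: 0.290
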