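# Frozen spectral-index formulas

Closed forms implemented in `R/spectral.R` and mirrored by the independent
test oracle (`tests/testthat/helper-oracle.R`). Bands are reflectances:
B = blue (475 nm), G = green (560 nm), R = red (668 nm),
RE = red-edge (717 nm), N = NIR (842 nm). Every division is guarded: a zero
denominator or a missing band yields nodata, never an infinity.

## Core registry (category VI unless noted)

| Acronym | Formula | Note |
|---|---|---|
| EVI    | `2.5 (N - R) / (N + 6R - 7.5B + 1)` | |
| SAVI   | `1.5 (N - R) / (N + R + 0.5)` | `(1 + L)(N - R)/(N + R + L)`, L = 0.5 |
| BGI    | `B / G` | |
| TVI    | `0.5 [120 (N - G) - 200 (R - G)]` | triangle area form |
| MCARI  | `[(RE - R) - 0.2 (RE - G)] (RE / R)` | red form |
| CREI   | `N / RE - 1` | red-edge chlorophyll index |
| PPR    | `(G - B) / (G + B)` | |
| GCI    | `N / G - 1` | green chlorophyll index |
| GNDRE  | `(RE - G) / (RE + G)` | |
| ARI    | `1 / G - 1 / RE` | canonical anthocyanin index (green, red-edge) |
| CCCI   | `[(N - RE)/(N + RE)] / [(N - R)/(N + R)]` | NDRE / NDVI |
| MCCI   | `(RE - R)/(RE + R) - (RE - G)/(RE + G)` | NDVIre - GNDRE |
| SR     | `N / R` | |
| NPPR   | `G / (B + R)` | |
| GARI   | `[N - (G - (B - R))] / [N + (G - (B - R))]` | |
| NPCI   | `(R - B) / (R + B)` | |
| VARIg  | `(G - R) / (G + R - B)` | |
| EVIre  | `2.5 (RE - R) / (RE + 6R - 7.5B + 1)` | red-edge substitution |
| SAVIre | `1.5 (RE - R) / (RE + R + 0.5)` | red-edge substitution |
| SIPI   | `(N - B) / (N - R)` | |
| MRESR  | `(N - B) / (RE - B)` | |
| RRI    | `RE / R` | |
| NDVIre | `(RE - R) / (RE + R)` | masking index |
| MCARI2 | `[(N - RE) - 0.2 (N - G)] (N / RE)` | red-edge form |
| TGI    | `-0.5 [190 (R - G) - 120 (R - B)]` | |
| HUE (CSI) | `acos{ 0.5 [(R-G) + (R-B)] / sqrt[(R-G)^2 + (R-B)(G-B)] }` in degrees, reflected to `360 - theta` when `B > G` | achromatic: 0 |

## Text-named extension set

| Acronym | Formula | Note |
|---|---|---|
| NDVI  | `(N - R) / (N + R)` | |
| NDRE  | `(N - RE) / (N + RE)` | |
| GNDVI | `(N - G) / (N + G)` | |
| WDRVI | `(0.2 N - R) / (0.2 N + R)` | alpha = 0.2 |
| TrVI  | `sqrt(NDVI + 0.5)` | nodata when NDVI < -0.5 |
| SAT (CSI) | `1 - 3 min(R,G,B) / (R + G + B)` | |
| INT (CSI) | `(R + G + B) / 3` | |
| REP (WV)  | `700 + 40 (R_i - R700) / (R740 - R700)`, `R_i = (R + N)/2`; `R700`, `R740` interpolated linearly between band centers 668/717 and 717/842 nm; clamped to [690, 750] | flat spectrum: nodata |
| REIP (WV) | as REP with `R_i = (R + 2 RE + N)/4` | |
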