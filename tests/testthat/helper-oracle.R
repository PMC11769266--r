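# Independent brute-force oracle for every registered spectral index,
# coded formula-by-formula from the frozen closed forms (FORMULAS.md),
# deliberately not sharing any code with the package implementation.

oracle_hue <- function(R, G, B) {
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  if (R + G + B == 0) return(NA_real_)
  if (den == 0) return(0)
  th <- acos(max(-1, min(1, num / den))) * 180 / pi
  if (B > G) 360 - th else th
}

oracle_index <- function(acr, b) {
  B <- b[["blue"]]; G <- b[["green"]]; R <- b[["red"]]
  RE <- b[["rededge"]]; N <- b[["nir"]]
  dv <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  switch(acr,
    EVI    = dv(2.5 * (N - R), N + 6 * R - 7.5 * B + 1),
    SAVI   = dv(1.5 * (N - R), N + R + 0.5),
    BGI    = dv(B, G),
    TVI    = 0.5 * (120 * (N - G) - 200 * (R - G)),
    MCARI  = { r <- dv(RE, R); if (is.na(r)) NA_real_ else
                 ((RE - R) - 0.2 * (RE - G)) * r },
    CREI   = dv(N, RE) - 1,
    PPR    = dv(G - B, G + B),
    GCI    = dv(N, G) - 1,
    GNDRE  = dv(RE - G, RE + G),
    ARI    = dv(1, G) - dv(1, RE),
    CCCI   = dv(dv(N - RE, N + RE), dv(N - R, N + R)),
    MCCI   = dv(RE - R, RE + R) - dv(RE - G, RE + G),
    SR     = dv(N, R),
    NPPR   = dv(G, B + R),
    GARI   = dv(N - (G - (B - R)), N + (G - (B - R))),
    NPCI   = dv(R - B, R + B),
    VARIg  = dv(G - R, G + R - B),
    EVIre  = dv(2.5 * (RE - R), RE + 6 * R - 7.5 * B + 1),
    SAVIre = dv(1.5 * (RE - R), RE + R + 0.5),
    SIPI   = dv(N - B, N - R),
    MRESR  = dv(N - B, RE - B),
    RRI    = dv(RE, R),
    NDVIre = dv(RE - R, RE + R),
    MCARI2 = { r <- dv(N, RE); if (is.na(r)) NA_real_ else
                 ((N - RE) - 0.2 * (N - G)) * r },
    TGI    = -0.5 * (190 * (R - G) - 120 * (R - B)),
    HUE    = oracle_hue(R, G, B),
    NDVI   = dv(N - R, N + R),
    NDRE   = dv(N - RE, N + RE),
    GNDVI  = dv(N - G, N + G),
    WDRVI  = dv(0.2 * N - R, 0.2 * N + R),
    TrVI   = { v <- dv(N - R, N + R)
               if (is.na(v) || v < -0.5) NA_real_ else sqrt(v + 0.5) },
    SAT    = if (R + G + B == 0) NA_real_ else
               if (R == G && G == B) 0 else 1 - 3 * min(R, G, B) / (R + G + B),
    INT    = if (R + G + B == 0) NA_real_ else (R + G + B) / 3,
    REP    = oracle_rep(R, RE, N, (R + N) / 2),
    REIP   = oracle_rep(R, RE, N, (R + 2 * RE + N) / 4),
    stop("oracle has no formula for ", acr)
  )
}

oracle_rep <- function(R, RE, N, r_infl) {
  r700 <- R + (700 - 668) / (717 - 668) * (RE - R)
  r740 <- RE + (740 - 717) / (842 - 717) * (N - RE)
  if (r740 - r700 == 0) return(NA_real_)
  min(750, max(690, 700 + 40 * (r_infl - r700) / (r740 - r700)))
}

random_band_vectors <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(blue = runif(n, 0.01, 0.9), green = runif(n, 0.01, 0.9),
             red = runif(n, 0.01, 0.9), rededge = runif(n, 0.01, 0.9),
             nir = runif(n, 0.01, 0.9))
}
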