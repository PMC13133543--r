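# shared test fixtures: a reduced canvas keeps raster tests fast while
# preserving the full geometry (all series members fit at 8 px/A)
small_canvas <- function(...) {
  default_canvas(width = 160L, height = 120L, scale = 8, origin = c(72, 70),
                 ...)
}

make_series <- function(df) {
  specs <- lapply(seq_len(nrow(df)), function(i)
    compound_spec(df$id[i], df$X[i], df$Y[i], df$R1[i], df$R2[i],
                  ic50_mg_per_L = if ("ic50" %in% names(df)) df$ic50[i]
                                  else NA_real_,
                  pic50 = if ("pic50" %in% names(df)) df$pic50[i]
                          else NA_real_))
  structure(specs, class = "compound_series")
}

# a small, varied sub-series used by encoder/pipeline unit tests
mini_series <- function() {
  make_series(data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l"),
    X = c("S", "S", "O", "CH", "S", "S", "O", "S", "S", "O", "CH", "S"),
    Y = c("CH", "CH", "CH", "S", "C", "CH", "CH", "CH", "CH", "CH", "S",
          "C"),
    R1 = c("H", "CF3", "F", "Cl", "CF3", "CH3", "Br", "F", "Cl", "CF3",
           "H", "F"),
    R2 = c("H", "H", "3-CH3", "H", "5-CH3", "3-Br", "H", "3,5-CH3", "3-Br",
           "3-CH3", "3-CH3", "5-CH3"),
    pic50 = c(5.3, 6.9, 6.4, 5.8, 7.0, 5.1, 5.5, 6.6, 5.9, 7.1, 5.4,
              6.5),
    stringsAsFactors = FALSE))
}
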