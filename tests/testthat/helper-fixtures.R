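# Small in-code fixtures shared across test files.

# perfectly bilaterally symmetric 8-landmark configuration (2 pairs + 4 midline)
symmetric_config_8 <- function(id = "sym1") {
  pairing <- make_pairing(rbind(c(1, 2), c(3, 4)), midline = 5:8)
  coords <- rbind(
    c(-1.0, 0.5, 0.2), c(1.0, 0.5, 0.2),
    c(-0.6, -0.8, 0.9), c(0.6, -0.8, 0.9),
    c(0, 1.2, 0.1), c(0, 0.3, -1.0), c(0, -0.5, 0.4), c(0, -1.1, -0.3)
  )
  landmark_config(id, coords, pairing = pairing)
}

# a valid two-row specimen table
tiny_specimens <- function() {
  data.frame(
    specimen_id = c("a1", "b2"),
    property = c("dingoes_rare", "dingoes_common"),
    sex = c("female", "male"),
    molar_index = c(10.5, 12.0),
    weight_kg = c(24.1, 55.0),
    pes_length_cm = c(30.2, 36.5),
    stringsAsFactors = FALSE
  )
}

# random rigid motion + positive scaling applied to a configuration matrix
rigid_scramble <- function(X, scale = NULL) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  s <- if (is.null(scale)) exp(rnorm(1, 0, 0.5)) else scale
  s * X %*% Q + matrix(rnorm(3, 0, 10), nrow(X), 3, byrow = TRUE)
}

# specimen table with prescribed counts, ages evenly spread over a range
counted_specimens <- function(n_f_rare, n_m_rare, n_f_common, n_m_common,
                              rare_range = c(1.5, 11),
                              common_range = c(3, 10.5)) {
  mk <- function(n, property, sex, range) {
    if (n == 0) return(NULL)
    age <- seq(range[1], range[2], length.out = n + 2)[2:(n + 1)]
    data.frame(
      specimen_id = sprintf("%s_%s_%02d", property, sex, seq_len(n)),
      property = property, sex = sex,
      molar_index = molar_index_from_age(age * 365.25),
      weight_kg = 20 + age, pes_length_cm = 25 + age,
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(
    mk(n_f_rare, "dingoes_rare", "female", rare_range),
    mk(n_m_rare, "dingoes_rare", "male", rare_range),
    mk(n_f_common, "dingoes_common", "female", common_range),
    mk(n_m_common, "dingoes_common", "male", common_range)
  )
  validate_specimens(df)$records
}
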