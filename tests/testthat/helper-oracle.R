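# Independent brute-force recount used as an oracle: plain double loops and
# hand month arithmetic, sharing no code with the package internals.

oracle_category <- function(code) {
  switch(code,
    live_birth_cesarean = "birth",
    live_birth_vaginal = "birth",
    stillbirth = "loss",
    miscarriage = "loss",
    ectopic = "loss",
    abortion = "abortion",
    stop("bad code")
  )
}

oracle_window <- function(interview_cm, label) {
  y <- 1900 + (interview_cm - 1) %/% 12
  if (label == "standard") {
    c((y - 5 - 1900) * 12 + 1, (y - 1 - 1900) * 12 + 12)
  } else if (label == "expanded") {
    c((y - 6 - 1900) * 12 + 1, interview_cm)
  } else {
    c(-Inf, interview_cm)
  }
}

# per-woman history-side count by explicit loop
oracle_ftf_counts <- function(coh, category, label) {
  resp <- coh$respondents
  preg <- coh$pregnancies
  out <- integer(nrow(resp))
  for (i in seq_len(nrow(resp))) {
    w <- oracle_window(resp$interview_cm[i], label)
    k <- 0L
    for (j in seq_len(nrow(preg))) {
      if (preg$id[j] != resp$id[i]) next
      if (isTRUE(preg$is_current[j])) next
      if (is.na(preg$end_cm[j])) next
      if (oracle_category(preg$outcome[j]) != category) next
      if (preg$end_cm[j] >= w[1] && preg$end_cm[j] <= w[2]) k <- k + 1L
    }
    out[i] <- k
  }
  out
}

oracle_ratio_counts <- function(coh, category, label) {
  resp <- coh$respondents
  acol <- paste0("acasi_", category)
  num <- 0L
  den <- 0L
  fcounts <- oracle_ftf_counts(coh, category, label)
  for (i in seq_len(nrow(resp))) {
    if (resp[[acol]][i] >= 1) num <- num + 1L
    if (fcounts[i] >= 1) den <- den + 1L
  }
  list(n_acasi = num, n_ftf = den,
       ratio = if (den > 0) num / den else NA_real_)
}

oracle_discordant <- function(coh, category) {
  resp <- coh$respondents
  acol <- paste0("acasi_", category)
  fcounts <- oracle_ftf_counts(coh, category, "standard")
  resp$id[resp[[acol]] >= 1 & fcounts == 0]
}
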