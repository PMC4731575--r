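# Independent brute-force oracles and small generators used across tests.
# These deliberately re-derive results by enumeration, not by calling the
# implementation paths they check.

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")

random_sequence <- function(n, residues = AA20) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# Substring-based digest oracle: a span [a, b] is a valid peptide iff both of
# its boundaries are cleavage boundaries and it contains <= max_missed
# internal cleavage sites.
oracle_digest <- function(sequence, protease, max_missed,
                          min_len = 1, max_len = Inf, keil = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  is_site <- function(i) {
    if (i < 1 || i >= n) return(FALSE)
    switch(protease,
           trypsin = aa[i] %in% c("K", "R") && !(keil && aa[i + 1] == "P"),
           argc = aa[i] == "R" && !(keil && aa[i + 1] == "P"),
           thermolysin = aa[i + 1] %in% c("L", "I", "A", "F", "V", "M"),
           pepsin = aa[i] %in% c("F", "L"))
  }
  out <- NULL
  for (a in 1:n) for (b in a:n) {
    len <- b - a + 1
    if (len < min_len || len > max_len) next
    if (!(a == 1 || is_site(a - 1))) next
    if (!(b == n || is_site(b))) next
    internal <- if (b > a) sum(vapply(a:(b - 1), is_site, logical(1))) else 0L
    if (internal > max_missed) next
    out <- rbind(out, data.frame(start = a, end = b,
                                 sequence = substr(sequence, a, b),
                                 missed_cleavages = internal,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), missed_cleavages = integer(0))
  out[order(out$start, out$end), , drop = FALSE]
}

# Quadruple-loop CHNO composition oracle with the same plausibility filters.
oracle_compositions <- function(delta, tol, n_max = 3, allow_radical = FALSE,
                                max_o_c = 1.2, max_n_c = 1.3) {
  mC <- 12; mH <- 1.007825032; mN <- 14.003074005; mO <- 15.99491462
  hi <- delta + tol
  out <- character(0)
  for (cc in 0:floor(hi / mC)) for (hh in 0:floor(hi / mH))
    for (nn in 0:min(n_max, floor(hi / mN))) for (oo in 0:floor(hi / mO)) {
      mass <- cc * mC + hh * mH + nn * mN + oo * mO
      if (abs(mass - delta) > tol) next
      if (hh > 2 * cc + 2 + nn) next
      if (cc > 0 && (oo > max_o_c * cc || nn > max_n_c * cc)) next
      r <- cc - hh / 2 + nn / 2 + 1
      if (r < 0) next
      if ((r %% 1 != 0) && !allow_radical) next
      out <- c(out, formula_string(element_counts(c = cc, h = hh,
                                                  n = nn, o = oo)))
    }
  sort(unique(out))
}

# Sliding-window S/TPxK motif oracle on a plain (offset-1) sequence.
oracle_stpxk <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  pos <- integer(0)
  if (n >= 4) for (i in 1:(n - 3)) {
    if (aa[i] %in% c("S", "T") && aa[i + 1] == "P" && aa[i + 3] == "K")
      pos <- c(pos, i)
  }
  pos
}

# Noiseless spectrum for a modified peptide: exact singly-charged b/y ladder.
exact_spectrum <- function(sequence, placements = NULL, charge = 2L,
                           title = "exact") {
  mp <- modified_peptide(sequence, placements)
  frags <- theoretical_fragments(mp, charges = 1L, include_internal = FALSE,
                                 losses = NULL)
  neutral <- peptide_mass_mp(mp)
  spectrum(title, (neutral + charge * PROTON_MASS) / charge, charge,
           cbind(frags$mz, rep(100, nrow(frags))))
}
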