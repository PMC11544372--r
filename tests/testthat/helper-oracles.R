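# Independent oracles used across test files.

# Signed fan-triangulation area: sum of cross-product triangle areas from
# the first vertex; equals the shoelace value for any vertex order.
fan_area <- function(f1, f2) {
  n <- length(f1)
  s <- 0
  for (i in 2:(n - 1)) {
    s <- s + ((f1[i] - f1[1]) * (f2[i + 1] - f2[1]) -
                (f1[i + 1] - f1[1]) * (f2[i] - f2[1])) / 2
  }
  abs(s)
}

# Brute-force phrase segmentation: enumerate all contiguous partitions of
# the words and keep the unique one in which every within-phrase gap is
# below the threshold and every between-phrase gap reaches it.
brute_force_phrases <- function(words, gap_threshold = 0.5) {
  n <- nrow(words)
  if (n == 1L) {
    return(list(1L))
  }
  gaps <- words$start[-1] - words$end[-n]
  # same 1 ns guard against floating-point timestamp noise as the rule
  splits <- gaps >= gap_threshold - 1e-9
  # each of the n-1 gaps is either a boundary or not; the rule fixes each
  # independently, so enumerate and filter
  valid <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    b <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
    if (all(b == splits)) {
      valid <- b
      break
    }
  }
  pid <- cumsum(c(TRUE, valid))
  unname(split(seq_len(n), pid))
}

# ANOVA-style distinctiveness oracle: per-dimension between/total sums of
# squares from stats::aov, combined across F1 and F2.
aov_distinctiveness <- function(tokens, exclude = "y:") {
  tok <- tokens[!(tokens$category %in% exclude), , drop = FALSE]
  ss <- function(y) {
    a <- stats::anova(stats::aov(y ~ factor(tok$category)))
    c(between = a$`Sum Sq`[1], total = sum(a$`Sum Sq`))
  }
  s1 <- ss(tok$f1)
  s2 <- ss(tok$f2)
  (s1[["between"]] + s2[["between"]]) / (s1[["total"]] + s2[["total"]])
}

# Small cohort plan used by most unit tests.
tiny_plan <- function(n_families = 6, phrases = 4, tokens = 2, ...) {
  cohort_plan(n_families = n_families, phrases_per_recording = phrases,
              tokens_per_category_per_session = tokens, ...)
}
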