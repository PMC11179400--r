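# Brute-force negation-scope oracle, independent of the package's matcher.
# Works directly on a token vector: a mention starting at token index `at`
# (spanning `term_len` tokens) is negated iff some cue token-sequence sits
# wholly inside the window of `w` tokens before (after) the mention with no
# scope terminator between the cue and the mention.
oracle_negated <- function(tokens, at, term_len, lexicon) {
  w <- lexicon$window_tokens
  terminators <- lexicon$scope_terminators
  cue_tokens <- function(cue) {
    m <- gregexpr("[.;:,]|[^ .;:,]+", cue, perl = TRUE)[[1]]
    substring(cue, m, m + attr(m, "match.length") - 1L)
  }
  # pre cues: enumerate every placement of every cue in the window
  for (cue in lexicon$negation_cues_pre) {
    ct <- cue_tokens(cue)
    k <- length(ct)
    for (end_pos in seq_len(at - 1L)) {
      start_pos <- end_pos - k + 1L
      if (start_pos < 1L) next
      if (at - start_pos > w) next                  # cue not fully in window
      if (!identical(tokens[start_pos:end_pos], ct)) next
      between <- if (end_pos + 1L <= at - 1L) tokens[(end_pos + 1L):(at - 1L)] else character(0)
      if (!any(between %in% terminators)) return(TRUE)
    }
  }
  last <- at + term_len - 1L
  for (cue in lexicon$negation_cues_post) {
    ct <- cue_tokens(cue)
    k <- length(ct)
    n <- length(tokens)
    for (start_pos in seq_len(n)) {
      if (start_pos <= last) next
      end_pos <- start_pos + k - 1L
      if (end_pos > n) next
      if (end_pos - last > w) next
      if (!identical(tokens[start_pos:end_pos], ct)) next
      between <- if (last + 1L <= start_pos - 1L) tokens[(last + 1L):(start_pos - 1L)] else character(0)
      if (!any(between %in% terminators)) return(TRUE)
    }
  }
  FALSE
}

# Enumerated cue x filler x term grammar used by the scope property suites.
# Returns a data.frame of generated sentences with the oracle's verdict.
negation_grammar_cases <- function(lexicon) {
  fillers <- list(character(0), "signs", c("signs", "of"),
                  c("any", "residual", "signs", "of"),
                  c("evidence", "whatsoever", "at", "this", "visit", "of"),
                  c("signs", ".", "there", "was"),
                  c("signs", "but", "evidence", "of"),
                  c("interval", "change", "in"),
                  c("new", "or", "worsening"))
  pre_cues <- c(NA, lexicon$negation_cues_pre)
  terms <- c("tear", "lens touch", "hyphema")
  post_tails <- list(character(0), c("was", "not", "seen"),
                     c("was", "noted"), c(".", "not", "noted"))
  grid <- expand.grid(cue = pre_cues, filler = seq_along(fillers),
                      term = terms, tail = seq_along(post_tails),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cue <- grid$cue[i]
    cue_tok <- if (is.na(cue)) character(0) else
      strsplit(cue, " ", fixed = TRUE)[[1]]
    term_tok <- strsplit(grid$term[i], " ", fixed = TRUE)[[1]]
    tokens <- c("patient", "had", cue_tok, fillers[[grid$filler[i]]],
                term_tok, post_tails[[grid$tail[i]]])
    at <- 2L + length(cue_tok) + length(fillers[[grid$filler[i]]]) + 1L
    list(tokens = tokens,
         text = paste(tokens, collapse = " "),
         term = grid$term[i],
         at = at,
         term_len = length(term_tok))
  })
  out
}
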