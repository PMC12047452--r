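# shared test helpers

# pathway from a bare code vector, with chained synthetic entities
pw_from_codes <- function(codes, id = "pw") {
  n <- length(codes)
  new_pathway(id,
              source = paste0(id, "_n", seq_len(n) - 1L),
              target = paste0(id, "_n", seq_len(n)),
              st_code = codes)
}

# uniformly random valid code string, assuming RNG is already seeded
random_code <- function(cap = 5L) {
  tab <- st_taxonomy()
  l1 <- sample(unique(tab$level1), 1L)
  l2s <- as.integer(tab$level2[tab$level1 == l1 & tab$level2 != "*"])
  l2 <- if (length(l2s) == 1L) l2s else sample(l2s, 1L)
  sprintf("%d.%d.%d.%d", l1, l2, sample.int(cap, 1L), sample.int(cap, 1L))
}

random_pathway <- function(len, id = "pw", cap = 5L) {
  pw_from_codes(vapply(seq_len(len), function(i) random_code(cap), character(1)),
                id = id)
}
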