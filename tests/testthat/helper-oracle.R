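# Brute-force chromosome oracle: the genome as an explicit per-bp label
# vector ("G<i>" for gene i, "I" for intergenic, "T<id>" for a TE copy).
# Insertion is literal vector splicing, excision is literal label removal,
# classification is a single lookup. Deliberately naive and independent of
# the package's segment machinery; only usable for tiny genomes.

oracle_genome <- function(gene_count = 3, gene_length = 10, te_length = 5,
                          intergenic_length = 7) {
  list(labels = c(rep(paste0("G", seq_len(gene_count) - 1), each = gene_length),
                  rep("I", intergenic_length)),
       te_length = te_length)
}

oracle_insert <- function(or, position, te_id) {
  or$labels <- append(or$labels, rep(paste0("T", te_id), or$te_length),
                      after = position)
  or
}

oracle_remove <- function(or, te_id) {
  or$labels <- or$labels[or$labels != paste0("T", te_id)]
  or
}

oracle_classify <- function(or, position) {
  lab <- or$labels[position + 1]
  if (lab == "I") {
    list(kind = "INTERGENIC", gene_index = NA_real_, te_id = NA_real_)
  } else if (startsWith(lab, "G")) {
    list(kind = "GENIC", gene_index = as.numeric(substring(lab, 2)),
         te_id = NA_real_)
  } else {
    list(kind = "WITHIN_TE", gene_index = NA_real_,
         te_id = as.numeric(substring(lab, 2)))
  }
}

# assert classify_site agrees with the oracle at every bp
expect_layout_identical <- function(genome, or) {
  expect_identical(genome_length(genome), as.numeric(length(or$labels)))
  for (pos in seq_along(or$labels) - 1) {
    got <- classify_site(genome, pos)
    want <- oracle_classify(or, pos)
    if (!identical(got, want)) {
      fail(sprintf("classify_site(%d): got %s, oracle %s", pos,
                   paste(unlist(got), collapse = "/"),
                   paste(unlist(want), collapse = "/")))
      return(invisible(FALSE))
    }
  }
  succeed()
  invisible(TRUE)
}

# a small genome with n seeded TEs for dynamics tests
tiny_genome <- function(n_tes = 1, gene_count = 3, gene_length = 10,
                        te_length = 5, intergenic_length = 20) {
  new_genome(gene_count, gene_length, te_length, n_tes, intergenic_length)
}
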