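# Spatially explicit chromosome model.
#
# The chromosome is a sequence of segments laid out left to right. The
# canonical layout is: all genes in index order as one genic block, then a
# single intergenic block. A TE insertion splices a new te_length-bp segment
# into whichever segment contains the insertion point, shifting all
# downstream coordinates; the split halves remember their offset into the
# original element so that excision restores the layout exactly and gene
# indices never drift. Coordinates are 0-based, half-open.

.SEG_GENIC <- 1L
.SEG_INTERGENIC <- 2L
.SEG_TE <- 3L

#' Create a host chromosome
#'
#' Builds a chromosome of `gene_count` genes laid out head to tail, followed
#' by a block of intergenic DNA, and seeds it with `initial_te_count` TE
#' copies placed uniformly at random in the intergenic space. Under the
#' standard study conditions genomes carry either 500 or 5000 genes and the
#' experiment starts from a single TE copy per host.
#'
#' @param gene_count number of genes (positive integer; 500 or 5000 in the
#'   standard configurations).
#' @param gene_length length of each gene in bp.
#' @param te_length length of one TE copy in bp.
#' @param initial_te_count number of TE copies to seed into intergenic DNA.
#' @param intergenic_length bp of initial non-genic, non-TE DNA. Defaults to
#'   10% of the genic bp.
#'
#' @return An object of class `te_genome`.
#' @export
new_genome <- function(gene_count, gene_length = 1000, te_length = 1000,
                       initial_te_count = 1, intergenic_length = NULL) {
  if (length(gene_count) != 1 || is.na(gene_count) || gene_count < 1 ||
      gene_count != floor(gene_count))
    stop("`gene_count` must be a positive integer")
  if (gene_length < 1 || gene_length != floor(gene_length))
    stop("`gene_length` must be a positive integer")
  if (te_length < 1 || te_length != floor(te_length))
    stop("`te_length` must be a positive integer")
  if (initial_te_count < 0 || initial_te_count != floor(initial_te_count))
    stop("`initial_te_count` must be a non-negative integer")
  if (is.null(intergenic_length))
    intergenic_length <- round(0.1 * gene_count * gene_length)
  if (intergenic_length < 1)
    stop("`intergenic_length` must be positive")

  g <- structure(
    list(
      gene_count = as.numeric(gene_count),
      gene_length = as.numeric(gene_length),
      te_length = as.numeric(te_length),
      intergenic_length = as.numeric(intergenic_length),
      # parallel segment vectors
      seg_kind = c(.SEG_GENIC, .SEG_INTERGENIC),
      seg_id = c(NA_real_, NA_real_),
      seg_off = c(0, 0),
      seg_len = c(gene_count * gene_length, as.numeric(intergenic_length)),
      # TE registry
      te_id = numeric(0),
      te_active = logical(0),
      te_nested = numeric(0),      # id of host TE for nested copies, NA otherwise
      disrupted_genes = numeric(0),
      next_te_id = 1
    ),
    class = "te_genome"
  )
  for (i in seq_len(initial_te_count)) {
    pos <- .sample_site_in(g, .SEG_INTERGENIC)
    g <- insert_te(g, pos)
  }
  g
}

# segment start coordinates (length n, 0-based)
.seg_starts <- function(genome) {
  n <- length(genome$seg_len)
  if (n == 0) return(numeric(0))
  cumsum(c(0, genome$seg_len[-n]))
}

#' Total chromosome length in bp
#'
#' Always equals `gene_count * gene_length + intergenic_length +
#' n_te * te_length`, where `n_te` counts every TE copy retained in the
#' sequence (including inactivated copies whose DNA persists).
#'
#' @param genome a `te_genome`.
#' @return total length in bp.
#' @export
genome_length <- function(genome) sum(genome$seg_len)

#' Genic bp of a chromosome
#' @param genome a `te_genome`.
#' @return total bp lying inside genes.
#' @export
genic_bp <- function(genome) {
  sum(genome$seg_len[genome$seg_kind == .SEG_GENIC])
}

#' Number of active TE copies
#' @param genome a `te_genome`.
#' @return count of TE copies able to transpose.
#' @export
active_te_count <- function(genome) sum(genome$te_active)

#' Classify a chromosome position
#'
#' Determines whether a bp position falls inside a gene, inside a TE copy, or
#' in intergenic DNA. Insertions only affect host fitness when they land
#' within a gene, so this classification drives the fitness machinery.
#'
#' @param genome a `te_genome`.
#' @param position 0-based bp coordinate, `0 <= position < genome_length()`.
#' @return a list with `kind` (one of `"GENIC"`, `"INTERGENIC"`,
#'   `"WITHIN_TE"`), and `gene_index` (0-based) or `te_id` as applicable.
#' @export
classify_site <- function(genome, position) {
  tl <- genome_length(genome)
  if (length(position) != 1 || is.na(position) || position < 0 || position >= tl)
    stop("`position` out of range [0, ", format(tl, scientific = FALSE), ")")
  starts <- .seg_starts(genome)
  i <- findInterval(position, starts)
  kind <- genome$seg_kind[i]
  if (kind == .SEG_GENIC) {
    idx <- (genome$seg_off[i] + (position - starts[i])) %/% genome$gene_length
    list(kind = "GENIC", gene_index = idx, te_id = NA_real_)
  } else if (kind == .SEG_TE) {
    list(kind = "WITHIN_TE", gene_index = NA_real_, te_id = genome$seg_id[i])
  } else {
    list(kind = "INTERGENIC", gene_index = NA_real_, te_id = NA_real_)
  }
}

# sample a uniform position restricted to segments of one kind
.sample_site_in <- function(genome, kind) {
  sel <- genome$seg_kind == kind
  w <- ifelse(sel, genome$seg_len, 0)
  tot <- sum(w)
  if (tot <= 0) stop("no sequence of the requested kind to insert into")
  j <- sample.int(length(w), 1L, prob = w)
  starts <- .seg_starts(genome)
  starts[j] + min(floor(stats::runif(1) * genome$seg_len[j]),
                  genome$seg_len[j] - 1)
}

#' Sample a TE insertion site under insertion bias
#'
#' Draws a bp position with every non-genic bp weighted 1 and every genic bp
#' weighted `insertion_bias`. `insertion_bias = 1` gives uniform sampling over
#' the chromosome; values below 1 steer insertions away from genes, and 0
#' excludes genes entirely. The probability of a genic landing is
#' `bias * G / (bias * G + N)` for `G` genic and `N` non-genic bp.
#'
#' @param genome a `te_genome`.
#' @param insertion_bias per-bp weight multiplier for genic positions, in
#'   `[0, 1]`.
#' @return a 0-based bp position.
#' @export
sample_insertion_site <- function(genome, insertion_bias) {
  if (length(insertion_bias) != 1 || is.na(insertion_bias) ||
      insertion_bias < 0 || insertion_bias > 1)
    stop("`insertion_bias` must be a single value in [0, 1]")
  w <- genome$seg_len * ifelse(genome$seg_kind == .SEG_GENIC, insertion_bias, 1)
  tot <- sum(w)
  if (tot <= 0) stop("no insertable sequence under this bias")
  j <- sample.int(length(w), 1L, prob = w)
  starts <- .seg_starts(genome)
  starts[j] + min(floor(stats::runif(1) * genome$seg_len[j]),
                  genome$seg_len[j] - 1)
}

# insertion with site report; public insert_te() wraps this
.insert_te_at <- function(genome, position, te_id = NULL, active = TRUE) {
  tl <- genome_length(genome)
  if (length(position) != 1 || is.na(position) || position < 0 || position >= tl)
    stop("`position` out of range [0, ", format(tl, scientific = FALSE), ")")
  if (is.null(te_id)) {
    te_id <- genome$next_te_id
  } else if (te_id %in% genome$te_id) {
    stop("duplicate te_id ", te_id)
  }
  starts <- .seg_starts(genome)
  i <- findInterval(position, starts)
  d <- position - starts[i]
  kind <- genome$seg_kind[i]

  site <- if (kind == .SEG_GENIC) {
    list(kind = "GENIC",
         gene_index = (genome$seg_off[i] + d) %/% genome$gene_length,
         te_id = NA_real_)
  } else if (kind == .SEG_TE) {
    list(kind = "WITHIN_TE", gene_index = NA_real_, te_id = genome$seg_id[i])
  } else {
    list(kind = "INTERGENIC", gene_index = NA_real_, te_id = NA_real_)
  }

  # splice: [i pre-part] [new TE] [i post-part]
  n <- length(genome$seg_len)
  pre <- seq_len(i - 1)
  post <- if (i < n) seq(i + 1, n) else integer(0)
  if (d == 0) {
    k_new <- c(genome$seg_kind[pre], .SEG_TE, genome$seg_kind[i], genome$seg_kind[post])
    id_new <- c(genome$seg_id[pre], te_id, genome$seg_id[i], genome$seg_id[post])
    off_new <- c(genome$seg_off[pre], 0, genome$seg_off[i], genome$seg_off[post])
    len_new <- c(genome$seg_len[pre], genome$te_length, genome$seg_len[i], genome$seg_len[post])
  } else {
    k_new <- c(genome$seg_kind[pre], genome$seg_kind[i], .SEG_TE, genome$seg_kind[i], genome$seg_kind[post])
    id_new <- c(genome$seg_id[pre], genome$seg_id[i], te_id, genome$seg_id[i], genome$seg_id[post])
    off_new <- c(genome$seg_off[pre], genome$seg_off[i], 0, genome$seg_off[i] + d, genome$seg_off[post])
    len_new <- c(genome$seg_len[pre], d, genome$te_length, genome$seg_len[i] - d, genome$seg_len[post])
  }
  genome$seg_kind <- k_new
  genome$seg_id <- id_new
  genome$seg_off <- off_new
  genome$seg_len <- len_new

  genome$te_id <- c(genome$te_id, te_id)
  genome$te_active <- c(genome$te_active, active)
  genome$te_nested <- c(genome$te_nested,
                        if (site$kind == "WITHIN_TE") site$te_id else NA_real_)
  if (site$kind == "GENIC" && !(site$gene_index %in% genome$disrupted_genes))
    genome$disrupted_genes <- c(genome$disrupted_genes, site$gene_index)
  if (te_id >= genome$next_te_id) genome$next_te_id <- te_id + 1
  list(genome = genome, te_id = te_id, site = site)
}

#' Insert a TE copy at a position
#'
#' Splices a `te_length`-bp TE copy into the chromosome at `position`,
#' shifting all downstream coordinates. A genic landing records the gene as
#' disrupted (permanently, for this lineage); a landing inside another TE
#' records the nesting relationship and has no fitness consequence.
#'
#' @param genome a `te_genome`.
#' @param position 0-based bp insertion point, `0 <= position <
#'   genome_length()`. The new copy occupies `[position, position +
#'   te_length)`.
#' @param te_id optional explicit copy id (defaults to the next free id;
#'   reusing an existing id is an error).
#' @return the updated `te_genome`.
#' @export
insert_te <- function(genome, position, te_id = NULL) {
  .insert_te_at(genome, position, te_id)$genome
}

# merge adjacent segments split from the same original element
.coalesce_segments <- function(genome) {
  n <- length(genome$seg_len)
  if (n < 2) return(genome)
  keep <- rep(TRUE, n)
  j <- 1 # index of current merged-run head
  for (i in 2:n) {
    same_id <- (is.na(genome$seg_id[j]) && is.na(genome$seg_id[i])) ||
      (!is.na(genome$seg_id[j]) && !is.na(genome$seg_id[i]) &&
         genome$seg_id[j] == genome$seg_id[i])
    if (genome$seg_kind[i] == genome$seg_kind[j] && same_id &&
        genome$seg_off[i] == genome$seg_off[j] + genome$seg_len[j]) {
      genome$seg_len[j] <- genome$seg_len[j] + genome$seg_len[i]
      keep[i] <- FALSE
    } else {
      j <- i
    }
  }
  genome$seg_kind <- genome$seg_kind[keep]
  genome$seg_id <- genome$seg_id[keep]
  genome$seg_off <- genome$seg_off[keep]
  genome$seg_len <- genome$seg_len[keep]
  genome
}

#' Excise a TE copy
#'
#' Removes the copy's DNA from the chromosome, shrinking the total length by
#' `te_length` and re-joining the flanking sequence. Copies nested inside the
#' removed TE are not deleted; they stay in place, re-anchored to the removal
#' point.
#'
#' @param genome a `te_genome`.
#' @param te_id id of the copy to remove.
#' @return the updated `te_genome`.
#' @export
remove_te <- function(genome, te_id) {
  k <- match(te_id, genome$te_id)
  if (is.na(k)) stop("no TE with id ", te_id)
  drop <- genome$seg_kind == .SEG_TE & !is.na(genome$seg_id) & genome$seg_id == te_id
  genome$seg_kind <- genome$seg_kind[!drop]
  genome$seg_id <- genome$seg_id[!drop]
  genome$seg_off <- genome$seg_off[!drop]
  genome$seg_len <- genome$seg_len[!drop]
  genome$te_id <- genome$te_id[-k]
  genome$te_active <- genome$te_active[-k]
  genome$te_nested <- genome$te_nested[-k]
  .coalesce_segments(genome)
}

# mark a copy inactive without touching its DNA (decayed copies keep their bp)
.deactivate_te <- function(genome, te_id) {
  k <- match(te_id, genome$te_id)
  if (is.na(k)) stop("no TE with id ", te_id)
  genome$te_active[k] <- FALSE
  genome
}

#' @export
print.te_genome <- function(x, ...) {
  cat("<te_genome> ", format(genome_length(x), big.mark = ","), " bp: ",
      format(x$gene_count, big.mark = ","), " genes x ", x$gene_length, " bp, ",
      format(x$intergenic_length, big.mark = ","), " bp intergenic, ",
      length(x$te_id), " TE copies (", sum(x$te_active), " active), ",
      length(x$disrupted_genes), " disrupted genes\n", sep = "")
  invisible(x)
}

#' Serialize a genome snapshot to JSON
#'
#' Debug aid: dumps the segment layout and TE registry.
#'
#' @param genome a `te_genome`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
genome_to_json <- function(genome, path = NULL) {
  obj <- list(
    gene_count = genome$gene_count, gene_length = genome$gene_length,
    te_length = genome$te_length, intergenic_length = genome$intergenic_length,
    total_length = genome_length(genome),
    segments = data.frame(kind = c("GENIC", "INTERGENIC", "TE")[genome$seg_kind],
                          id = genome$seg_id, offset = genome$seg_off,
                          length = genome$seg_len),
    tes = data.frame(te_id = genome$te_id, active = genome$te_active,
                     nested_in = genome$te_nested),
    disrupted_genes = genome$disrupted_genes
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
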