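# IUPAC nucleotide ambiguity classes. Motif 'N' matches any base including an
# ambiguous 'N' in the sequence; every other code matches concrete bases only,
# so a sequence 'N' never satisfies a non-N motif position.
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

validate_iupac <- function(motif, min_len = 6, max_len = 8) {
  motif <- toupper(motif)
  chars <- strsplit(motif, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    stop("Invalid IUPAC character '", bad[1], "' in motif '", motif, "'.",
         call. = FALSE)
  }
  if (nchar(motif) < min_len || nchar(motif) > max_len) {
    stop("Motif '", motif, "' has length ", nchar(motif),
         "; expected ", min_len, "-", max_len, ".", call. = FALSE)
  }
  motif
}

# One uniformly sampled concrete expansion (used when planting motifs).
sample_iupac_expansion <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    cls[sample.int(length(cls), 1)]
  }, character(1)), collapse = "")
}

#' Expand an IUPAC motif to all concrete DNA words
#'
#' @param motif IUPAC string (any length; the scanner itself enforces 6-8).
#' @return Character vector of all concrete \{A,C,G,T\} expansions.
#' @examples
#' expand_iupac("RYCGAC")
#' @export
expand_iupac <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    stop("Invalid IUPAC character '", bad[1], "' in motif '", motif, "'.",
         call. = FALSE)
  }
  grid <- expand.grid(IUPAC_CLASSES[chars], stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(chars)), drop = FALSE], 1, function(r) {
    paste(rev(r), collapse = "")
  })
}

#' Build a window matcher for a degenerate IUPAC motif
#'
#' Returns a predicate over \{A,C,G,T,N\} strings: a window matches iff every
#' position's base lies in the motif's IUPAC class at that position. An 'N'
#' in the *sequence* matches only a motif 'N' (an ambiguous base is never
#' credited to a concrete motif position).
#'
#' @param motif IUPAC string of length 6-8.
#' @return A function `f(windows)` returning a logical vector.
#' @examples
#' m <- iupac_matcher("ACGTGKC")
#' m(c("ACGTGTC", "ACGTGGC", "ACGTGAC"))
#' @export
iupac_matcher <- function(motif) {
  motif <- validate_iupac(motif)
  pat <- iupac_regex(motif)
  function(windows) {
    nchar(windows) == nchar(motif) & grepl(pat, toupper(windows), perl = TRUE)
  }
}

# Regex over the {A,C,G,T,N} sequence alphabet implementing the matcher
# semantics above (motif 'N' additionally admits a sequence 'N').
iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  classes <- vapply(chars, function(ch) {
    allowed <- IUPAC_CLASSES[[ch]]
    if (ch == "N") allowed <- c(allowed, "N")
    if (length(allowed) == 1) allowed else paste0("[", paste(allowed, collapse = ""), "]")
  }, character(1))
  paste0("^", paste(classes, collapse = ""), "$")
}

count_motif_hits <- function(sequences, motif) {
  # overlapping occurrences via zero-width lookahead
  pat <- sub("\\$$", ")", sub("^\\^", "(?=", iupac_regex(motif)))
  hits <- gregexpr(pat, sequences, perl = TRUE)
  vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), integer(1))
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector over \{A,C,G,T,N\} (case-insensitive).
#' @return Reverse-complemented uppercase sequences.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Scan promoters for degenerate motifs
#'
#' Slides every motif over every promoter, counting all (overlapping) start
#' offsets. With `strands = "both"` the reverse complement of each promoter
#' is scanned as well; presence is the OR over strands and `match_count`
#' sums both strands. Scanning is case-insensitive.
#'
#' @param promoters Tibble with `gene_id` and `sequence` columns (as from
#'   [read_promoters()] or [simulate_promoters()]).
#' @param motifs Tibble with a `motif` column (and optional `label`), or a
#'   character vector of IUPAC 6-8-mers.
#' @param strands `"both"` (default) or `"forward"`.
#' @return A tibble: `gene_id`, `motif`, `match_count`, `present`.
#' @export
scan_promoters <- function(promoters, motifs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(motifs)) motifs <- tibble::tibble(motif = motifs)
  motif_vec <- vapply(motifs$motif, validate_iupac, character(1))
  if (length(motif_vec) == 0) {
    return(tibble::tibble(gene_id = character(), motif = character(),
                          match_count = integer(), present = logical()))
  }
  seqs <- toupper(promoters$sequence)
  rc <- if (strands == "both") reverse_complement(seqs)
  purrr::map_dfr(motif_vec, function(m) {
    cnt <- count_motif_hits(seqs, m)
    if (strands == "both") cnt <- cnt + count_motif_hits(rc, m)
    tibble::tibble(
      gene_id = promoters$gene_id,
      motif = m,
      match_count = cnt,
      present = cnt >= 1L
    )
  })
}

#' Per-module enrichment of promoter motifs
#'
#' Hypergeometric upper-tail test of motif presence per (module, motif) pair:
#' `k` module genes carrying the motif among `n` module genes, against `K`
#' carriers in a background of `N` genes. Benjamini-Hochberg FDR is applied
#' jointly across all (module, motif) pairs; a pair is enriched when
#' `fdr < fdr_threshold`, and the enrichment score is `-log10(fdr)`.
#'
#' @param matches Match table from [scan_promoters()].
#' @param modules Module assignment tibble with `feature_id` and `module`
#'   columns (as from [detect_coresponse_modules()]); the `"unassigned"`
#'   sink is not tested.
#' @param background Character vector of background gene ids (default: all
#'   genes in `matches`). Every module gene must have a scanned promoter.
#' @param fdr_threshold Enrichment cutoff on the adjusted p (default 0.01).
#' @return A tibble: `module`, `motif`, `k`, `n`, `K`, `N`, `p`, `fdr`,
#'   `score`, `enriched`.
#' @export
module_cre_enrichment <- function(matches, modules, background = NULL,
                                  fdr_threshold = 0.01) {
  scanned <- unique(matches$gene_id)
  if (is.null(background)) background <- scanned
  background <- unique(background)
  missing_bg <- setdiff(background, scanned)
  if (length(missing_bg) > 0) {
    stop("Background genes lack scanned promoters: ",
         paste(utils::head(missing_bg, 5), collapse = ", "),
         if (length(missing_bg) > 5) ", ...", call. = FALSE)
  }
  mod_tbl <- modules[modules$module != "unassigned", , drop = FALSE]
  missing_mod <- setdiff(mod_tbl$feature_id, background)
  if (length(missing_mod) > 0) {
    stop("Module genes missing from the background/promoter set: ",
         paste(utils::head(missing_mod, 5), collapse = ", "),
         if (length(missing_mod) > 5) ", ...", call. = FALSE)
  }
  present <- matches[matches$present & matches$gene_id %in% background, ]
  N <- length(background)
  motif_levels <- unique(matches$motif)
  carriers <- split(present$gene_id, factor(present$motif, levels = motif_levels))
  out <- purrr::map_dfr(split(mod_tbl$feature_id, mod_tbl$module), function(genes) {
    n <- length(genes)
    purrr::map_dfr(motif_levels, function(m) {
      K <- length(carriers[[m]])
      k <- sum(genes %in% carriers[[m]])
      tibble::tibble(motif = m, k = k, n = n, K = K, N = N,
                     p = hypergeometric_upper(k, n, K, N))
    })
  }, .id = "module")
  out$fdr <- bh_fdr(out$p)
  out$score <- -log10(out$fdr)
  out$enriched <- out$fdr < fdr_threshold
  dplyr::arrange(out, .data$fdr, .data$module, .data$motif)
}

#' Bubble-plot overview of module motif enrichment
#'
#' One circle per enriched (module, motif) pair: size is the number of
#' module genes carrying the motif, opacity the enrichment score
#' `-log10(FDR)`.
#'
#' @param enrichment Result of [module_cre_enrichment()].
#' @param enriched_only Show only pairs passing the FDR threshold (default).
#' @return A ggplot object.
#' @export
plot_cre_enrichment <- function(enrichment, enriched_only = TRUE) {
  df <- if (enriched_only) enrichment[enrichment$enriched, ] else enrichment
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$motif)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k, alpha = .data$score),
                        colour = "#7b3294") +
    ggplot2::scale_size_area(name = "genes with CRE") +
    ggplot2::scale_alpha_continuous(name = expression(-log[10](FDR))) +
    ggplot2::labs(x = "module", y = "cis-regulatory element") +
    ggplot2::theme_minimal()
}
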