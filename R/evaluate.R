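## --- helpers -------------------------------------------------------------

as_inclusion_list <- function(x) {
  lapply(x, function(e) if (inherits(e, "isoform")) e$inclusion else
    as.integer(e))
}

## shared exonic nucleotides between two inclusion vectors
nt_shared <- function(gene, a, b) {
  sum(gene$subexons$length[as.logical(a) & as.logical(b)])
}

nt_size <- function(gene, a) sum(gene$subexons$length[as.logical(a)])

## exon-level "overlapping" relation: identified exon e1 overlaps annotated
## exon e2 when their intersection covers at least half of e2
exon_overlapping <- function(e1, e2) {
  ov <- pmax(0, pmin(e1["end"], e2["end"]) - pmax(e1["start"], e2["start"]))
  ov >= 0.5 * (e2["end"] - e2["start"])
}

harmonic_f <- function(precision, recall) {
  if (precision > 0 && recall > 0) 2 / (1 / precision + 1 / recall) else 0
}

gene_evaluation <- function(level, precision, recall) {
  structure(list(level = level, precision = precision, recall = recall,
                 f_score = harmonic_f(precision, recall)),
            class = "gene_evaluation")
}

#' @export
print.gene_evaluation <- function(x, ...) {
  cat(sprintf("%s-level: precision %.4f, recall %.4f, F %.4f\n",
              x$level, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Pair identified with annotated isoforms by best overlap
#'
#' Each query isoform is scored against every target by `score_fn` (an
#' overlap percentage relative to the query); queries are ranked by their
#' best score, descending, and paired greedily without replacement with
#' their best still-unclaimed target. When there are more queries than
#' targets only the top `length(targets)` queries are paired; the rest
#' remain unpaired (false positives on the precision side, misses on the
#' recall side). Ties are broken by input order.
#'
#' @param queries,targets Lists of binary inclusion vectors (or
#'   [isoform]s).
#' @param score_fn `function(query, target)` returning an overlap
#'   percentage.
#' @return Data.frame with columns `query`, `target` (indices; `NA` target
#'   for unpaired queries), one row per query, in input order.
#' @export
match_pairs <- function(queries, targets, score_fn) {
  queries <- as_inclusion_list(queries)
  targets <- as_inclusion_list(targets)
  k <- length(queries); r <- length(targets)
  pair <- rep(NA_integer_, k)
  if (k == 0L || r == 0L)
    return(data.frame(query = seq_len(k), target = pair))
  S <- matrix(0, k, r)
  for (i in seq_len(k)) for (j in seq_len(r))
    S[i, j] <- score_fn(queries[[i]], targets[[j]])
  best <- apply(S, 1L, max)
  ord <- order(-best, seq_len(k))          # rank by best overlap, stable
  taken <- logical(r)
  for (i in ord[seq_len(min(k, r))]) {
    avail <- which(!taken)
    j <- avail[which.max(S[i, avail])]
    pair[i] <- j
    taken[j] <- TRUE
  }
  data.frame(query = seq_len(k), target = pair)
}

## generic two-sided evaluation: per-query rates from a rate_fn, averaged
two_sided <- function(level, identified, annotated, score_fn, rate_fn) {
  identified <- as_inclusion_list(identified)
  annotated <- as_inclusion_list(annotated)
  side <- function(queries, targets) {
    if (length(queries) == 0L) return(0)
    mp <- match_pairs(queries, targets, score_fn)
    rates <- vapply(seq_along(queries), function(i) {
      j <- mp$target[i]
      if (is.na(j)) 0 else rate_fn(queries[[i]], targets[[j]])
    }, numeric(1))
    mean(rates)
  }
  gene_evaluation(level, side(identified, annotated),
                  side(annotated, identified))
}

#' Nucleotide-level precision, recall and F score
#'
#' Identified isoforms are paired with annotated isoforms by shared
#' nucleotides ([match_pairs()]); a paired identified isoform's precision
#' is `shared nucleotides / nucleotides in the identified isoform`, and the
#' gene precision is the mean over all identified isoforms (unpaired ones
#' scoring 0). Recall is the symmetric construction on the annotated side;
#' F is the harmonic mean (0 when either rate is 0).
#'
#' @param identified,annotated Lists of binary inclusion vectors or
#'   [isoform]s on `gene`.
#' @param gene A [gene_model].
#' @return A `gene_evaluation` (fields `level`, `precision`, `recall`,
#'   `f_score`).
#' @export
evaluate_nucleotide <- function(identified, annotated, gene) {
  score <- function(q, t) {
    sz <- nt_size(gene, q)
    if (sz == 0) 0 else nt_shared(gene, q, t) / sz
  }
  two_sided("nucleotide", identified, annotated, score, score)
}

#' Exon-level precision, recall and F score
#'
#' Exons are the maximal runs of genomically contiguous included subexons.
#' Two exons are *overlapping* when the identified exon covers at least
#' 50 % of the annotated exon. A paired identified isoform's precision is
#' `overlapping exons / exons in the identified isoform`; recall is the
#' annotated-side analogue; averaging and F as at the nucleotide level.
#'
#' @inheritParams evaluate_nucleotide
#' @return A `gene_evaluation`.
#' @export
evaluate_exon <- function(identified, annotated, gene) {
  exons_of <- function(inc) isoform_exons(gene, inc)
  ## fraction of q's exons standing in the overlap relation with some exon
  ## of t; the 50% threshold is always relative to the ANNOTATED exon, so
  ## the relation's direction is fixed by `annotated_is_target`
  frac_hit <- function(q, t, annotated_is_target) {
    qex <- exons_of(q); tex <- exons_of(t)
    if (nrow(qex) == 0L) return(0)
    hit <- vapply(seq_len(nrow(qex)), function(i)
      nrow(tex) > 0L && any(vapply(seq_len(nrow(tex)), function(j) {
        if (annotated_is_target)
          exon_overlapping(unlist(qex[i, ]), unlist(tex[j, ]))
        else
          exon_overlapping(unlist(tex[j, ]), unlist(qex[i, ]))
      }, logical(1))), logical(1))
    sum(hit) / nrow(qex)
  }
  score_prec <- function(q, t) frac_hit(q, t, annotated_is_target = TRUE)
  score_rec <- function(q, t) frac_hit(q, t, annotated_is_target = FALSE)
  identified <- as_inclusion_list(identified)
  annotated <- as_inclusion_list(annotated)
  side <- function(queries, targets, fn) {
    if (length(queries) == 0L) return(0)
    mp <- match_pairs(queries, targets, fn)
    mean(vapply(seq_along(queries), function(i) {
      j <- mp$target[i]
      if (is.na(j)) 0 else fn(queries[[i]], targets[[j]])
    }, numeric(1)))
  }
  gene_evaluation("exon", side(identified, annotated, score_prec),
                  side(annotated, identified, score_rec))
}

## transcript-level exact structural match: equal exon counts and each
## ordered exon pair overlapping (>= 50% of the annotated exon)
transcripts_matched <- function(gene, id_inc, ann_inc) {
  a <- isoform_exons(gene, id_inc)
  b <- isoform_exons(gene, ann_inc)
  if (nrow(a) != nrow(b) || nrow(a) == 0L) return(FALSE)
  all(vapply(seq_len(nrow(a)), function(i)
    exon_overlapping(unlist(a[i, ]), unlist(b[i, ])), logical(1)))
}

#' Transcript-level precision, recall and F score
#'
#' An identified and an annotated isoform are *matched* when they have the
#' same number of exons and every exon, taken in order, satisfies the
#' exon-level overlap rule. Precision is the fraction of identified
#' isoforms matched with some annotated isoform; recall the fraction of
#' annotated isoforms matched with some identified isoform; F the harmonic
#' mean.
#'
#' @inheritParams evaluate_nucleotide
#' @return A `gene_evaluation`.
#' @export
evaluate_transcript <- function(identified, annotated, gene) {
  identified <- as_inclusion_list(identified)
  annotated <- as_inclusion_list(annotated)
  if (length(identified) == 0L || length(annotated) == 0L)
    return(gene_evaluation("transcript", 0, 0))
  M <- outer(seq_along(identified), seq_along(annotated),
             Vectorize(function(i, j)
               transcripts_matched(gene, identified[[i]], annotated[[j]])))
  gene_evaluation("transcript", mean(apply(M, 1L, any)),
                  mean(apply(M, 2L, any)))
}

#' Evaluate one gene at all three levels
#'
#' @inheritParams evaluate_nucleotide
#' @return Data.frame with one row per level and columns `level`,
#'   `precision`, `recall`, `f_score`.
#' @export
evaluate_gene <- function(identified, annotated, gene) {
  evs <- list(evaluate_nucleotide(identified, annotated, gene),
              evaluate_exon(identified, annotated, gene),
              evaluate_transcript(identified, annotated, gene))
  do.call(rbind, lapply(evs, function(e)
    data.frame(level = e$level, precision = e$precision, recall = e$recall,
               f_score = e$f_score)))
}
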