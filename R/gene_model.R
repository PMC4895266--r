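#' Construct a gene model from subexon coordinates
#'
#' A gene model is the atomic description of one gene used throughout the
#' package: an ordered set of non-overlapping *subexons*, the exonic
#' intervals between two adjacent splice sites. All isoforms of the gene are
#' expressed as binary inclusion vectors over these subexons.
#'
#' Coordinates are 0-based half-open internally; GTF import/export converts
#' to and from the 1-based inclusive convention.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome (sequence) name.
#' @param strand `"+"` or `"-"`. The strand is carried through to GTF output
#'   but subexons are always ordered left-to-right genomically.
#' @param starts,ends Integer vectors of 0-based half-open subexon
#'   coordinates, sorted by start, pairwise non-overlapping.
#' @return An object of class `gene_model` with elements `gene_id`, `chrom`,
#'   `strand`, `subexons` (data.frame with `index`, `start`, `end`,
#'   `length`), `n` (subexon count) and `contiguous` (logical of length
#'   `n - 1`; `TRUE` where consecutive subexons abut with no intron).
#' @export
gene_model <- function(gene_id, chrom, strand = "+", starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("need at least one subexon with matching starts/ends")
  if (any(ends <= starts))
    stop("subexon end must exceed start")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(diff(starts) <= 0) || any(starts[-1] < ends[-length(ends)]))
    stop("subexons must be sorted and non-overlapping")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  n <- length(starts)
  structure(list(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    subexons = data.frame(index = seq_len(n), start = starts, end = ends,
                          length = ends - starts),
    n = n,
    contiguous = if (n > 1L) ends[-n] == starts[-1L] else logical(0)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d subexons, %d bp exonic\n",
              x$gene_id, x$chrom, x$strand, x$n, sum(x$subexons$length)))
  invisible(x)
}

#' Construct an isoform
#'
#' An isoform (transcript) is a binary subexon-inclusion vector over a gene
#' model: 1 means the subexon is part of the mature transcript.
#'
#' @param gene_id Gene identifier.
#' @param inclusion Binary (0/1) vector; at least one subexon included.
#' @param label Transcript label.
#' @return An object of class `isoform`.
#' @export
isoform <- function(gene_id, inclusion, label = NA_character_) {
  inclusion <- as.integer(inclusion)
  if (!all(inclusion %in% c(0L, 1L))) stop("inclusion must be binary")
  if (sum(inclusion) < 1L) stop("isoform must include at least one subexon")
  structure(list(gene_id = as.character(gene_id), inclusion = inclusion,
                 label = as.character(label)), class = "isoform")
}

#' Binary inclusion vector as a compact string
#'
#' @param inclusion Binary vector (or an `isoform`).
#' @return A string such as `"10111111"`.
#' @export
inclusion_string <- function(inclusion) {
  if (inherits(inclusion, "isoform")) inclusion <- inclusion$inclusion
  paste(as.integer(inclusion), collapse = "")
}

#' @rdname inclusion_string
#' @param x String of 0/1 characters.
#' @export
parse_inclusion <- function(x) {
  ch <- strsplit(x, "")[[1]]
  if (length(ch) == 0L || !all(ch %in% c("0", "1")))
    stop("not a binary inclusion string: ", x)
  as.integer(ch)
}

## Merge consecutive included subexons that are genomically contiguous into
## exon intervals (0-based half-open). Returns data.frame(start, end).
isoform_exons <- function(gene, inclusion) {
  idx <- which(as.logical(inclusion))
  if (length(idx) == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
  se <- gene$subexons
  brk <- c(TRUE, !(diff(idx) == 1L & gene$contiguous[idx[-length(idx)]]))
  grp <- cumsum(brk)
  data.frame(
    start = tapply(se$start[idx], grp, min),
    end = tapply(se$end[idx], grp, max),
    row.names = NULL
  )
}

#' Load gene models and annotated isoforms from a GTF file
#'
#' Derives each gene's subexon structure from its annotated exons: splice
#' sites are the pooled distinct exon starts and ends, and subexons are the
#' maximal intervals of the exon union lying between consecutive sites.
#' Every annotated transcript is then re-expressed as a binary inclusion
#' vector over these subexons.
#'
#' @param annotation_path Path to a GTF file (Ensembl dialect: `gene_id` and
#'   `transcript_id` attributes on exon features).
#' @return A named list (one element per gene) of lists with elements
#'   `gene` (a [gene_model]) and `isoforms` (list of [isoform]).
#' @export
load_gene_models <- function(annotation_path) {
  gr <- tryCatch(
    rtracklayer::import(annotation_path, format = "gtf"),
    error = function(e) stop("malformed GTF '", annotation_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  tid <- as.character(S4Vectors::mcols(gr)$transcript_id)
  if (anyNA(gid) || anyNA(tid))
    stop("GTF exon feature lacks gene_id or transcript_id attribute")
  out <- list()
  for (g in unique(gid)) {
    sel <- gid == g
    # to 0-based half-open
    st0 <- GenomicRanges::start(gr)[sel] - 1
    en0 <- GenomicRanges::end(gr)[sel]
    sites <- sort(unique(c(st0, en0)))
    cand_s <- sites[-length(sites)]
    cand_e <- sites[-1L]
    # keep intervals fully inside the exon union
    covered <- vapply(seq_along(cand_s), function(i)
      any(st0 <= cand_s[i] & en0 >= cand_e[i]), logical(1))
    strand_g <- as.character(GenomicRanges::strand(gr)[sel][1])
    if (!strand_g %in% c("+", "-")) strand_g <- "+"
    gm <- gene_model(g, as.character(GenomicRanges::seqnames(gr)[sel][1]),
                     strand_g, cand_s[covered], cand_e[covered])
    isos <- lapply(unique(tid[sel]), function(tr) {
      tsel <- sel & tid == tr
      ts <- GenomicRanges::start(gr)[tsel] - 1
      te <- GenomicRanges::end(gr)[tsel]
      inc <- integer(gm$n)
      for (e in seq_along(ts)) {
        hit <- which(gm$subexons$start >= ts[e] & gm$subexons$end <= te[e])
        cov <- sum(gm$subexons$length[hit])
        if (cov != te[e] - ts[e])
          stop("transcript '", tr, "' has an exon not decomposable into ",
               "whole subexons of gene '", g, "'")
        inc[hit] <- 1L
      }
      isoform(g, inc, tr)
    })
    out[[g]] <- list(gene = gm, isoforms = isos)
  }
  out
}

#' Write isoform candidates for one gene as a GTF file
#'
#' One transcript per candidate; consecutive included subexons that are
#' genomically contiguous are merged into single exon features. Coordinates
#' are emitted 1-based inclusive per GTF convention, so the output
#' round-trips through [load_gene_models()].
#'
#' @param gene A [gene_model].
#' @param candidates List of [isoform] objects or binary inclusion vectors
#'   of length `gene$n`.
#' @param out_path Output file path.
#' @param labels Optional transcript labels; defaults to
#'   `<gene_id>.cand<i>`.
#' @return `out_path`, invisibly.
#' @export
write_candidates_gtf <- function(gene, candidates, out_path, labels = NULL) {
  incs <- lapply(candidates, function(cc)
    if (inherits(cc, "isoform")) cc$inclusion else as.integer(cc))
  if (is.null(labels))
    labels <- sprintf("%s.cand%d", gene$gene_id, seq_along(incs))
  if (length(incs) == 0L) {
    writeLines(c("##gff-version 2",
                 sprintf("## no candidates for gene %s", gene$gene_id)),
               out_path)
    return(invisible(out_path))
  }
  rows <- list()
  for (i in seq_along(incs)) {
    inc <- incs[[i]]
    if (length(inc) != gene$n)
      stop("candidate ", i, " has inclusion length ", length(inc),
           " but gene has ", gene$n, " subexons")
    if (sum(inc) == 0L) stop("candidate ", i, " has all-zero inclusion")
    ex <- isoform_exons(gene, inc)
    rows[[i]] <- data.frame(start = ex$start + 1, end = ex$end,
                            transcript_id = labels[i])
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    gene$chrom, IRanges::IRanges(tab$start, tab$end), strand = gene$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- gene$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  rtracklayer::export(gr, out_path, format = "gtf")
  invisible(out_path)
}
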