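# Promoter-level p53 target analysis: RPKM transform, expressed-gene
# universe, paired per-individual fold changes averaged per group,
# strand-aware 5,000 bp upstream windows intersected with ChIP-seq peaks,
# a size-matched shuffled background and a two-sample KS comparison of the
# log2 fold-change ECDFs. All genomic intervals are 0-based half-open
# internally (BED convention); GTF input is converted on read.

# -- annotation / peak IO ------------------------------------------------

#' Read gene annotation from a TSV or GTF file
#'
#' TSV columns: `gene_id`, `chrom`, `start`, `end`, `strand`, `length`
#' (0-based half-open coordinates). GTF `gene` records are converted from
#' 1-based inclusive to internal 0-based half-open; the gene span length is
#' used as `length_bp` unless the file is a TSV with an explicit column.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gtf"` (guessed from the extension by default).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `length_bp`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand", "length")
    if (!all(need %in% names(df)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    ann <- data.frame(gene_id = as.character(df$gene_id),
                      chrom = as.character(df$chrom),
                      start = as.integer(df$start), end = as.integer(df$end),
                      strand = as.character(df$strand),
                      length_bp = as.integer(df$length),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", TRUE)]
    if (!length(f)) stop("no gene records in GTF")
    gid <- vapply(f, function(x) {
      m <- regmatches(x[9], regexec('gene_id "([^"]+)"', x[9]))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }, "")
    ann <- data.frame(gene_id = gid,
                      chrom = vapply(f, `[`, "", 1L),
                      start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
                      end = as.integer(vapply(f, `[`, "", 5L)),
                      strand = vapply(f, `[`, "", 7L),
                      stringsAsFactors = FALSE)
    ann$length_bp <- ann$end - ann$start
  }
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (any(ann$start >= ann$end)) stop("annotation has start >= end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("unknown strand value(s): ", paste(setdiff(unique(ann$strand),
                                                    c("+", "-")), collapse = ","))
  if (any(ann$length_bp <= 0)) stop("gene lengths must be positive")
  invisible(ann)
}

#' Read a BED3+ peak file (0-based half-open, as is)
#'
#' @param path BED file.
#' @return data.frame: `chrom`, `start`, `end`.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = as.character(df[[1L]]),
                      start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                      stringsAsFactors = FALSE)
  if (any(peaks$start >= peaks$end)) stop("peak file has start >= end")
  peaks
}

# -- expression ----------------------------------------------------------

#' Assemble a paired expression table
#'
#' @param counts gene x sample matrix of non-negative integer counts
#'   (rownames = gene ids, colnames = sample ids).
#' @param meta data.frame with `sample_id`, `individual`, `group`
#'   (`Ctrl`/`HD`), `treatment` (`DMSO`/`branaplam`); every individual must
#'   contribute exactly one sample per treatment arm.
#' @param gene_lengths named vector of transcript-model lengths in bp.
#' @return an `ExpressionTable` list.
#' @export
expression_table <- function(counts, meta, gene_lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("sample_id", "individual", "group", "treatment")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!setequal(meta$sample_id, colnames(counts)))
    stop("metadata samples and count columns differ")
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  for (ind in unique(meta$individual)) {
    arms <- sort(meta$treatment[meta$individual == ind])
    if (length(arms) != 2L || anyDuplicated(arms))
      stop(sprintf("individual %s lacks a complete DMSO/treated pair", ind))
  }
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) stop("gene lengths missing for some genes")
  if (any(gl <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts, meta = meta, gene_lengths = gl),
            class = "ExpressionTable")
}

#' RPKM transform
#'
#' `rpkm[g, s] = counts[g, s] / (length_kb[g]) / (library_size[s] / 1e6)`
#' with library size the per-sample total count.
#'
#' @param table an `ExpressionTable`.
#' @return RPKM matrix with the dimensions of the count matrix.
#' @export
compute_rpkm <- function(table) {
  stopifnot(inherits(table, "ExpressionTable"))
  libsize <- colSums(table$counts)
  if (any(libsize == 0)) stop("zero library size")
  sweep(table$counts / (table$gene_lengths / 1000), 2L, libsize / 1e6, "/")
}

#' Expressed-gene universe
#'
#' Genes whose mean RPKM across all samples is strictly greater than
#' `cutoff` (default 0.5).
#'
#' @param table an `ExpressionTable`.
#' @param cutoff mean-RPKM cutoff.
#' @param rpkm optional precomputed RPKM matrix.
#' @return character vector of gene ids.
#' @export
expressed_universe <- function(table, cutoff = 0.5, rpkm = NULL) {
  if (is.null(rpkm)) rpkm <- compute_rpkm(table)
  rownames(rpkm)[rowMeans(rpkm) > cutoff]
}

#' Group-averaged paired fold changes
#'
#' Per individual, the treated/vehicle RPKM ratio per gene (with a
#' pseudocount added to both arms); the group value is the arithmetic mean
#' of the per-individual ratios (mean of ratios, not ratio of means), and
#' its log2 is reported for ECDFs.
#'
#' @param table `ExpressionTable`.
#' @param group `"Ctrl"` or `"HD"`.
#' @param pseudocount RPKM pseudocount (default 0.1). With `pseudocount = 0`,
#'   genes hitting 0/0 or x/0 in any individual are dropped (NA) and counted
#'   in a message.
#' @param genes optional gene subset (default: all genes in the table).
#' @param treated_label,vehicle_label treatment arm labels.
#' @return data.frame: `gene_id`, `fc` (group mean fold change), `log2_fc`.
#' @export
group_fold_changes <- function(table, group, pseudocount = 0.1, genes = NULL,
                               treated_label = "branaplam",
                               vehicle_label = "DMSO") {
  stopifnot(inherits(table, "ExpressionTable"))
  rpkm <- compute_rpkm(table)
  if (!is.null(genes)) rpkm <- rpkm[genes, , drop = FALSE]
  meta <- table$meta
  inds <- unique(meta$individual[meta$group == group])
  if (!length(inds)) stop("no individuals in group ", group)
  fcs <- vapply(inds, function(ind) {
    st <- meta$sample_id[meta$individual == ind & meta$treatment == treated_label]
    sv <- meta$sample_id[meta$individual == ind & meta$treatment == vehicle_label]
    if (length(st) != 1L || length(sv) != 1L)
      stop(sprintf("individual %s misses one arm of the pair", ind))
    (rpkm[, st] + pseudocount) / (rpkm[, sv] + pseudocount)
  }, numeric(nrow(rpkm)))
  fcs <- matrix(fcs, nrow = nrow(rpkm))
  fcs[!is.finite(fcs)] <- NA
  fc <- rowMeans(fcs)
  n_dropped <- sum(is.na(fc))
  if (n_dropped > 0)
    message(n_dropped, " gene(s) dropped (undefined fold change at pseudocount 0)")
  out <- data.frame(gene_id = rownames(rpkm), fc = fc, log2_fc = log2(fc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!is.na(out$fc), ]
}

# -- promoter windows and peak intersection ------------------------------

#' Strand-aware 5' upstream promoter windows
#'
#' For `+` genes, `[max(0, start - span), start)`; for `-` genes,
#' `[end, end + span)`; 0-based half-open. The gene "start" is the
#' strand-aware 5' end.
#'
#' @param genes annotation data.frame (see [read_gene_annotation()]).
#' @param span window size in bp (default 5000).
#' @param strand_aware set `FALSE` for the strand-naive literal reading
#'   (always upstream of the smaller coordinate).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`.
#' @export
upstream_windows <- function(genes, span = 5000L, strand_aware = TRUE) {
  validate_annotation(genes)
  plus <- if (strand_aware) genes$strand == "+" else rep(TRUE, nrow(genes))
  ws <- ifelse(plus, pmax(0L, genes$start - span), genes$end)
  we <- ifelse(plus, genes$start, genes$end + span)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(ws), end = as.integer(we),
                    stringsAsFactors = FALSE)
  out[out$start < out$end, ]
}

#' Genes whose upstream window overlaps at least one peak
#'
#' Half-open overlap test (>= 1 bp); each gene reported once regardless of
#' how many peaks hit its window (the `u = TRUE` semantics of bedtools-style
#' intersection). Chromosomes present in only one of the two inputs trigger
#' a warning listing them.
#'
#' @param windows interval data.frame from [upstream_windows()].
#' @param peaks peak data.frame (`chrom`, `start`, `end`).
#' @return character vector of gene ids.
#' @export
genes_with_peak <- function(windows, peaks) {
  only_w <- setdiff(unique(windows$chrom), unique(peaks$chrom))
  only_p <- setdiff(unique(peaks$chrom), unique(windows$chrom))
  if (length(only_w) || length(only_p))
    warning("chromosomes absent from one input: ",
            paste(c(only_w, only_p), collapse = ","))
  hits <- character(0)
  for (ch in intersect(unique(windows$chrom), unique(peaks$chrom))) {
    w <- windows[windows$chrom == ch, ]
    p <- peaks[peaks$chrom == ch, ]
    # half-open [start, end) mapped to 1-based closed [start+1, end]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(w$start + 1L, w$end),
      IRanges::IRanges(p$start + 1L, p$end), minoverlap = 1L)
    hits <- c(hits, w$gene_id[unique(S4Vectors::queryHits(ov))])
  }
  unique(hits)
}

#' Size-matched shuffled background gene set
#'
#' Uniform sample of `n` genes without replacement from the universe,
#' reproducible under `seed`.
#'
#' @param universe character vector of gene ids.
#' @param n background size.
#' @param seed integer seed.
#' @return character vector of `n` gene ids.
#' @export
shuffled_background <- function(universe, n, seed) {
  if (n > length(universe))
    stop("background size exceeds the universe")
  set.seed(as.integer(seed))
  sample(universe, n, replace = FALSE)
}

# -- KS test -------------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`; two-sided p-value from the asymptotic
#' Kolmogorov distribution at effective size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples (non-empty).
#' @return a `KSResult` list: `statistic`, `p_value`, `n_target` (= size of
#'   `a`), `n_background` (= size of `b`).
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("empty sample in KS test")
  pooled <- sort(c(a, b))
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  d <- max(abs(fa - fb))
  neff <- na * nb / (na + nb)
  p <- kolmogorov_sf(sqrt(neff) * d)
  structure(list(statistic = d, p_value = p,
                 n_target = na, n_background = nb),
            class = "KSResult")
}

# survival function of the Kolmogorov distribution,
# Q(x) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 x^2), clamped to (0, 1]
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- seq_len(101L)
  q <- 2 * sum((-1)^(k - 1L) * exp(-2 * k^2 * x^2))
  min(1, max(q, .Machine$double.xmin))
}

#' @export
print.KSResult <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_target, x$n_background))
  invisible(x)
}

# -- composed analysis ---------------------------------------------------

#' p53 target vs shuffled-background fold-change comparison
#'
#' Composes the full promoter-target analysis for one group: expressed-gene
#' universe, strand-aware upstream windows intersected with peaks (targets
#' restricted to the universe), a size-matched shuffled background drawn from
#' the universe, group-averaged paired log2 fold changes for both sets, the
#' two-sample KS test and ECDF curve coordinates.
#'
#' @param table `ExpressionTable`.
#' @param genes annotation data.frame.
#' @param peaks peak data.frame.
#' @param group `"Ctrl"` or `"HD"`.
#' @param span upstream window size in bp.
#' @param cutoff expressed-universe mean-RPKM cutoff.
#' @param pseudocount fold-change pseudocount.
#' @param seed seed for the shuffled background.
#' @return list: `targets`, `background` (gene ids), `target_fc`,
#'   `background_fc` (data.frames from [group_fold_changes()]), `ks`
#'   (`KSResult`), `ecdf` (data.frame `log2_fc`, `ecdf`, `set`).
#' @export
target_vs_background_analysis <- function(table, genes, peaks,
                                          group = "Ctrl", span = 5000L,
                                          cutoff = 0.5, pseudocount = 0.1,
                                          seed = 1L) {
  universe <- expressed_universe(table, cutoff = cutoff)
  windows <- upstream_windows(genes, span = span)
  targets <- intersect(genes_with_peak(windows, peaks), universe)
  if (!length(targets)) stop("no expressed target genes found")
  background <- shuffled_background(universe, length(targets), seed = seed)
  fc_all <- group_fold_changes(table, group, pseudocount = pseudocount,
                               genes = universe)
  tfc <- fc_all[fc_all$gene_id %in% targets, ]
  bfc <- fc_all[fc_all$gene_id %in% background, ]
  ks <- ks_two_sample(tfc$log2_fc, bfc$log2_fc)
  ecdf_df <- rbind(
    data.frame(log2_fc = sort(tfc$log2_fc),
               ecdf = seq_along(tfc$log2_fc) / nrow(tfc), set = "target"),
    data.frame(log2_fc = sort(bfc$log2_fc),
               ecdf = seq_along(bfc$log2_fc) / nrow(bfc), set = "background"))
  list(targets = targets, background = background,
       target_fc = tfc, background_fc = bfc, ks = ks, ecdf = ecdf_df)
}

#' Venn-region counts for two or three gene panels
#'
#' @param set_a,set_b,set_c character vectors (one identifier namespace);
#'   `set_c` optional.
#' @return list with `counts` (named integer vector per disjoint region)
#'   and `members` (the region membership lists).
#' @export
gene_panel_overlap <- function(set_a, set_b, set_c = NULL) {
  a <- unique(set_a); b <- unique(set_b)
  if (is.null(set_c)) {
    members <- list(a_only = setdiff(a, b), b_only = setdiff(b, a),
                    ab = intersect(a, b))
  } else {
    cc <- unique(set_c)
    members <- list(
      a_only = setdiff(a, union(b, cc)),
      b_only = setdiff(b, union(a, cc)),
      c_only = setdiff(cc, union(a, b)),
      ab = setdiff(intersect(a, b), cc),
      ac = setdiff(intersect(a, cc), b),
      bc = setdiff(intersect(b, cc), a),
      abc = Reduce(intersect, list(a, b, cc)))
  }
  list(counts = vapply(members, length, 0L), members = members)
}
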