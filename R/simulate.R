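# Seeded generators for every input modality, each emitting machine-readable
# ground truth next to the data so that all pipeline stages are testable
# without external downloads. One top-level seed derives per-modality child
# seeds through a fixed counter scheme, so adding a generator never perturbs
# existing fixtures.

#' Derive a reproducible child seed from a top-level seed
#'
#' Lehmer-style mixing, keeping results inside the 32-bit integer range.
#'
#' @param seed top-level integer seed.
#' @param stream counter / stream index (>= 0).
#' @return integer child seed.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stream) %% 2147483647)
}

# stamp a filled disk of radius r at (r0, c0) into logical matrix `m`
stamp_disk <- function(m, r0, c0, r) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- max(1L, floor(r0 - r)):min(nr, ceiling(r0 + r))
  cols <- max(1L, floor(c0 - r)):min(nc, ceiling(c0 + r))
  sub <- outer(rows - r0, cols - c0, function(a, b) a^2 + b^2) <= r^2
  m[rows, cols] <- m[rows, cols] | sub
  m
}

disk_sel <- function(nr, nc, r0, c0, r) {
  stamp_disk(matrix(FALSE, nr, nc), r0, c0, r)
}

# -- neurite images ------------------------------------------------------

#' Generate synthetic neurite fields with known disintegration truth
#'
#' Neurites are drawn as smoothed random-walk tubes of the given width at a
#' uniform base intensity; a fraction `fragmentation` of neurite pixels is
#' elevated to `swelling_multiplier * base_intensity` in contiguous
#' bead-like runs along the tube, emulating fragmented/swollen segments;
#' Gaussian read noise is added on top of a constant camera offset. Each
#' image carries its true neurite mask, the elevated-pixel mask and the
#' realized disintegration fraction.
#'
#' @param n_images number of fields to generate.
#' @param image_size side of the square field, px.
#' @param n_neurites tubes per field.
#' @param neurite_width tube width in px.
#' @param base_intensity neurite fluorescence level.
#' @param background camera offset of non-neurite pixels.
#' @param noise_sd Gaussian read-noise SD.
#' @param fragmentation fraction of neurite pixels elevated, in `[0, 1]`.
#' @param swelling_multiplier elevation factor (> 1).
#' @param bead_radius radius of one elevated bead, px.
#' @param seed integer seed.
#' @return list of per-image lists: `image` (`ChannelImage`), `truth_mask`,
#'   `elevated_mask` (logical matrices), `truth_fraction`.
#' @export
make_neurite_images <- function(n_images = 10L, image_size = 192L,
                                n_neurites = 5L, neurite_width = 6L,
                                base_intensity = 100, background = 8,
                                noise_sd = 5, fragmentation = 0,
                                swelling_multiplier = 2, bead_radius = 6L,
                                seed = 1L) {
  stopifnot(fragmentation >= 0, fragmentation <= 1, swelling_multiplier > 1)
  lapply(seq_len(n_images), function(i) {
    set.seed(child_seed(seed, 100L + i))
    n <- image_size
    truth <- matrix(FALSE, n, n)
    half_w <- neurite_width / 2
    paths <- list()
    for (k in seq_len(n_neurites)) {
      r0 <- stats::runif(1, n * 0.1, n * 0.9)
      c0 <- stats::runif(1, n * 0.1, n * 0.9)
      ang <- stats::runif(1, 0, 2 * pi)
      pts <- matrix(0, 0, 2)
      for (step in seq_len(4L * n)) {
        ang <- ang + stats::rnorm(1, 0, 0.03)  # gently curving tubes
        r0 <- r0 + sin(ang); c0 <- c0 + cos(ang)
        if (r0 < 2 || r0 > n - 1 || c0 < 2 || c0 > n - 1) break
        pts <- rbind(pts, c(r0, c0))
        truth <- stamp_disk(truth, r0, c0, half_w)
      }
      paths[[k]] <- pts
    }
    elevated <- matrix(FALSE, n, n)
    total <- sum(truth)
    if (fragmentation > 0 && total > 0) {
      all_pts <- do.call(rbind, paths)
      ord <- sample(nrow(all_pts))
      j <- 1L
      while (sum(elevated) < fragmentation * total && j <= nrow(all_pts)) {
        p <- all_pts[ord[j], ]
        cand <- elevated | (disk_sel(n, n, p[1], p[2], bead_radius) & truth)
        # keep whichever bead count lands closest to the requested fraction
        if (abs(sum(cand) - fragmentation * total) >
            abs(sum(elevated) - fragmentation * total) && j > 1L) break
        elevated <- cand
        j <- j + 1L
      }
    }
    img <- matrix(background, n, n)
    img[truth] <- base_intensity
    img[elevated] <- swelling_multiplier * base_intensity
    img <- img + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    img <- pmax(img, 0)
    list(image = channel_image(img, channel = "tubulin"),
         truth_mask = truth, elevated_mask = elevated,
         truth_fraction = if (total > 0) sum(elevated) / total else NA_real_)
  })
}

# -- nucleus / NPM1 images -----------------------------------------------

#' Generate synthetic DAPI/tubulin/NPM1 fields with known NPM1 translocation
#'
#' Non-overlapping nuclei are placed at random; a designated fraction lies
#' inside the neuron (tubulin) area. Each nucleus holds one nucleolus. NPM1
#' intensity starts at `nucleolar_intensity` inside the nucleolus and
#' `nucleoplasm_intensity` elsewhere in the nucleus; the translocation
#' parameter `s` in `[0, 1]` moves both linearly toward the common
#' equalized level so that the total nuclear NPM1 is conserved exactly at
#' every `s` (complete dispersal at `s = 1`). Organelle boundaries are sharp
#' (no optical blur is emulated); Gaussian read noise is drawn from a
#' separate stream so the noise realization is identical across `s` at a
#' fixed seed.
#'
#' @param n_nuclei nuclei per field.
#' @param image_size field side, px.
#' @param nucleus_radius,nucleolus_radius disk radii, px.
#' @param nucleolar_intensity,nucleoplasm_intensity NPM1 levels at `s = 0`.
#' @param translocation `s` in `[0, 1]`.
#' @param neuronal_fraction fraction of nuclei inside the neuron area.
#' @param noise_sd Gaussian read-noise SD (all channels).
#' @param seed integer seed.
#' @return list: `dapi`, `tubulin`, `npm1` (`ChannelImage`s), `truth` —
#'   a list with `nuclei` (centers and `neuronal` flags), `nucleus_labels`,
#'   `nucleolus_labels` (matrices), `ratio` (the constructed
#'   nucleoplasm/nucleolar intensity ratio), `total_npm1_noiseless`.
#' @export
make_nucleus_images <- function(n_nuclei = 8L, image_size = 288L,
                                nucleus_radius = 30, nucleolus_radius = 8,
                                nucleolar_intensity = 200,
                                nucleoplasm_intensity = 50,
                                translocation = 0, neuronal_fraction = 1,
                                noise_sd = 3, seed = 1L) {
  stopifnot(nucleolus_radius < nucleus_radius,
            translocation >= 0, translocation <= 1)
  n <- image_size
  set.seed(child_seed(seed, 200L))
  # jittered-grid placement: non-overlapping by construction
  margin <- nucleus_radius + 3
  k <- ceiling(sqrt(n_nuclei))
  usable <- n - 2 * margin
  pitch <- usable / k
  jitter <- (pitch - (2 * nucleus_radius + 4)) / 2
  if (jitter < 0)
    stop("infeasible packing: could not place all nuclei at this density")
  jitter <- min(jitter, pitch / 4)
  grid <- expand.grid(r = seq_len(k), c = seq_len(k))
  grid <- grid[sample(nrow(grid), n_nuclei), ]
  centers <- cbind(
    margin + (grid$r - 0.5) * pitch + stats::runif(n_nuclei, -jitter, jitter),
    margin + (grid$c - 0.5) * pitch + stats::runif(n_nuclei, -jitter, jitter))
  neuronal <- rep(FALSE, n_nuclei)
  neuronal[seq_len(round(neuronal_fraction * n_nuclei))] <- TRUE
  nucleus_labels <- matrix(0L, n, n)
  nucleolus_labels <- matrix(0L, n, n)
  tubulin <- matrix(5, n, n)
  for (k in seq_len(n_nuclei)) {
    sel <- disk_sel(n, n, centers[k, 1], centers[k, 2], nucleus_radius)
    nucleus_labels[sel] <- k
    # nucleolus offset a little from the nucleus center
    off <- stats::runif(2, -0.3, 0.3) * nucleus_radius
    nsel <- disk_sel(n, n, centers[k, 1] + off[1], centers[k, 2] + off[2],
                     nucleolus_radius)
    nucleolus_labels[nsel & sel] <- k
    if (neuronal[k]) {
      # cytoplasmic tubulin covers the soma, including above/below the nucleus
      soma <- disk_sel(n, n, centers[k, 1], centers[k, 2], nucleus_radius + 10)
      tubulin[soma] <- 70
    }
  }
  dapi <- matrix(4, n, n)
  dapi[nucleus_labels > 0L] <- 120
  an <- sum(nucleolus_labels > 0L) / n_nuclei
  ap <- sum(nucleus_labels > 0L & nucleolus_labels == 0L) / n_nuclei
  eq <- (nucleolar_intensity * an + nucleoplasm_intensity * ap) / (an + ap)
  s <- translocation
  i_nucleolus <- nucleolar_intensity + s * (eq - nucleolar_intensity)
  i_nucleoplasm <- nucleoplasm_intensity + s * (eq - nucleoplasm_intensity)
  npm1 <- matrix(5, n, n)
  npm1[nucleus_labels > 0L] <- i_nucleoplasm
  npm1[nucleolus_labels > 0L] <- i_nucleolus
  total_noiseless <- sum(npm1[nucleus_labels > 0L])
  set.seed(child_seed(seed, 201L))  # separate noise stream, shared across s
  noise <- function() matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  out_ch <- function(m, tag) channel_image(pmax(m + noise(), 0), channel = tag)
  list(dapi = out_ch(dapi, "dapi"),
       tubulin = out_ch(tubulin, "tubulin"),
       npm1 = out_ch(npm1, "npm1"),
       truth = list(
         centers = centers, neuronal = neuronal,
         nucleus_labels = nucleus_labels, nucleolus_labels = nucleolus_labels,
         nucleolar_intensity = i_nucleolus,
         nucleoplasm_intensity = i_nucleoplasm,
         ratio = i_nucleoplasm / i_nucleolus,
         total_npm1_noiseless = total_noiseless))
}

# -- expression + peaks --------------------------------------------------

#' Generate a paired RNA-seq count dataset with an injected target shift
#'
#' Paired DMSO/treated samples per individual in two groups (Ctrl and HD),
#' negative-binomial counts around per-gene log-normal baselines; for a
#' designated target gene set the treated-arm expectation is multiplied by
#' `2^delta`. Gene lengths are log-normal. Individuals carry mild
#' library-size factors.
#'
#' @param n_genes total genes.
#' @param n_individuals individuals per group (each with 2 samples).
#' @param target_size number of designated target genes.
#' @param delta injected log2 fold-change shift on targets under treatment.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline
#'   expected counts.
#' @param seed integer seed.
#' @return list: `table` (`ExpressionTable`), `annotation` (data.frame as
#'   from [read_gene_annotation()]), `targets` (gene ids).
#' @export
make_expression_dataset <- function(n_genes = 2000L, n_individuals = 4L,
                                    target_size = 200L, delta = 0,
                                    dispersion = 0.05,
                                    base_meanlog = log(200), base_sdlog = 1,
                                    seed = 1L) {
  set.seed(child_seed(seed, 300L))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  lens <- pmax(200L, as.integer(round(stats::rlnorm(n_genes, log(1500), 0.6))))
  names(lens) <- gene_ids
  base_mu <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  targets <- sample(gene_ids, target_size)
  groups <- c("Ctrl", "HD")
  meta <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(seq_len(n_individuals), function(i)
      data.frame(sample_id = sprintf("%s_%d_%s", g, i, c("DMSO", "branaplam")),
                 individual = sprintf("%s_%d", g, i), group = g,
                 treatment = c("DMSO", "branaplam"),
                 stringsAsFactors = FALSE)))))
  counts <- matrix(0L, n_genes, nrow(meta),
                   dimnames = list(gene_ids, meta$sample_id))
  is_target <- gene_ids %in% targets
  for (j in seq_len(nrow(meta))) {
    sf <- stats::rlnorm(1, 0, 0.1)
    mu <- base_mu * sf
    if (meta$treatment[j] == "branaplam") mu[is_target] <- mu[is_target] * 2^delta
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  # tile genes along two toy chromosomes, random strand, 20 kb spacing
  chrom <- rep(c("chr1", "chr2"), length.out = n_genes)
  pos_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- 10000L + (pos_on_chrom - 1L) * 20000L
  ann <- data.frame(gene_id = gene_ids, chrom = chrom,
                    start = start, end = start + 2000L,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    length_bp = lens, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(table = expression_table(counts, meta, lens),
       annotation = ann, targets = targets)
}

#' Place ChIP-seq-like peaks upstream of designated target genes
#'
#' A fraction of the targets receives one peak placed inside its 5'
#' upstream window; decoy peaks are placed uniformly on the toy genome,
#' rejecting any position overlapping an upstream window of any gene. Peaks
#' wider than their window are shrunk with a warning.
#'
#' @param annotation gene annotation data.frame.
#' @param targets gene ids to receive peaks.
#' @param fraction fraction of targets actually given a peak.
#' @param decoy_count number of decoy peaks.
#' @param peak_width peak width in bp.
#' @param span upstream window size used for placement.
#' @param seed integer seed.
#' @return list: `peaks` (data.frame `chrom`, `start`, `end`),
#'   `peaked_targets` (gene ids that truly received a peak).
#' @export
make_peaks <- function(annotation, targets, fraction = 1, decoy_count = 100L,
                       peak_width = 200L, span = 5000L, seed = 1L) {
  stopifnot(all(targets %in% annotation$gene_id))
  set.seed(child_seed(seed, 400L))
  windows <- upstream_windows(annotation, span = span)
  rownames(windows) <- windows$gene_id
  chosen <- if (fraction >= 1) targets else
    sample(targets, round(fraction * length(targets)))
  peaks <- NULL
  for (g in chosen) {
    w <- windows[g, ]
    pw <- peak_width
    if (w$end - w$start < pw) {
      warning("window smaller than peak width for ", g, "; peak shrunk")
      pw <- w$end - w$start
    }
    s <- if (w$end - pw > w$start)
      sample(seq.int(w$start, w$end - pw), 1L) else w$start
    peaks <- rbind(peaks, data.frame(chrom = w$chrom, start = s, end = s + pw,
                                     stringsAsFactors = FALSE))
  }
  chrom_len <- tapply(c(windows$end, annotation$end),
                      c(windows$chrom, annotation$chrom), max)
  n_dec <- 0L; tries <- 0L
  while (n_dec < decoy_count && tries < decoy_count * 50L) {
    tries <- tries + 1L
    ch <- sample(names(chrom_len), 1L)
    s <- sample.int(as.integer(chrom_len[[ch]]), 1L)
    w <- windows[windows$chrom == ch, ]
    if (any(pmax(w$start, s) < pmin(w$end, s + peak_width))) next
    peaks <- rbind(peaks, data.frame(chrom = ch, start = s, end = s + peak_width,
                                     stringsAsFactors = FALSE))
    n_dec <- n_dec + 1L
  }
  if (is.null(peaks))
    peaks <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  list(peaks = peaks[order(peaks$chrom, peaks$start), , drop = FALSE],
       peaked_targets = chosen)
}

# -- FACS events ---------------------------------------------------------

#' Generate synthetic EdU/DAPI flow-cytometry events with known fractions
#'
#' DNA intensities are drawn from log-normal modes at the 2n and 4n levels
#' (S-phase events uniform between the modes); EdU intensities come from a
#' log-normal positive distribution for S-phase events and a log-normal
#' negative (background) distribution otherwise.
#'
#' @param n_events number of events.
#' @param fractions length-3 vector `(g0g1, s, g2m)` summing to 1.
#' @param mode_2n,mode_4n DNA-stain mode locations.
#' @param cv_2n,cv_4n coefficients of variation of the DNA modes.
#' @param edu_neg_meanlog,edu_neg_sdlog,edu_pos_meanlog,edu_pos_sdlog
#'   log-normal parameters of the EdU distributions.
#' @param seed integer seed.
#' @return list: `events` (data.frame `dna_intensity`, `edu_intensity`,
#'   `phase`), `fractions` (the specified truth).
#' @export
make_facs_events <- function(n_events = 20000L,
                             fractions = c(0.55, 0.30, 0.15),
                             mode_2n = 100, mode_4n = 200,
                             cv_2n = 0.05, cv_4n = 0.04,
                             edu_neg_meanlog = log(10), edu_neg_sdlog = 0.4,
                             edu_pos_meanlog = log(300), edu_pos_sdlog = 0.35,
                             seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  set.seed(child_seed(seed, 500L))
  phase <- sample(c("G0G1", "S", "G2M"), n_events, replace = TRUE,
                  prob = fractions)
  dna <- numeric(n_events)
  dna[phase == "G0G1"] <- stats::rlnorm(sum(phase == "G0G1"),
                                        log(mode_2n), cv_2n)
  dna[phase == "G2M"] <- stats::rlnorm(sum(phase == "G2M"),
                                       log(mode_4n), cv_4n)
  dna[phase == "S"] <- stats::runif(sum(phase == "S"), mode_2n, mode_4n)
  edu <- numeric(n_events)
  edu[phase == "S"] <- stats::rlnorm(sum(phase == "S"),
                                     edu_pos_meanlog, edu_pos_sdlog)
  edu[phase != "S"] <- stats::rlnorm(sum(phase != "S"),
                                     edu_neg_meanlog, edu_neg_sdlog)
  list(events = data.frame(dna_intensity = dna, edu_intensity = edu,
                           phase = phase, stringsAsFactors = FALSE),
       fractions = stats::setNames(fractions, c("g0g1", "s", "g2m")))
}
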