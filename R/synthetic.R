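#' Configuration for the synthetic matched-multiome generator
#'
#' The generator emulates a small matched scRNA/scATAC tumor cohort: two
#' "male patient" samples and two "female comparator" samples, four cell
#' types (malignant epithelium, macrophages, fibroblasts, endothelium),
#' patient-specific tumor transcriptomes, shared stromal/immune profiles,
#' planted copy-number segments, planted distal-enhancer-to-gene links with
#' a tunable metacell-level correlation, planted doublets and low-quality
#' cells, and hard-zero sex-specific genes. The synthetic genome is two 10-Mb
#' chromosomes tiled at 500 bp (40,000 tiles, 2,000 genes plus 10
#' mitochondrial genes): chromosome 1 carries the 100 planted enhancer
#' blocks, chromosome 2 the cell-type marker, latent-program, sex and
#' copy-number genes.
#'
#' @param n_cells_per_sample Cells per sample and modality (default 750).
#' @param link_effect_r Target metacell-level correlation of planted links
#'   (default 0.7); 0 removes all coupling.
#' @param n_links Number of planted enhancer-gene links (default 100; every
#'   third link is a tumor link with two target genes, the rest are lineage
#'   links with one, interleaved along the genome).
#' @param doublet_rate Fraction of cells that are averaged cross-type
#'   doublets (default 0.05).
#' @param low_quality_rate Fraction of cells with failing QC profiles
#'   (default 0.10).
#' @param rna_depth_meanlog,rna_depth_sdlog Log-normal RNA depth (defaults
#'   log(6000), 0.25; floored at 2500 for sound cells).
#' @param atac_depth_meanlog,atac_depth_sdlog Log-normal ATAC depth
#'   (defaults log(2500), 0.25; floored at 1200 for sound cells).
#' @param gamma_rna,gamma_atac Latent-factor effect sizes on the log scale
#'   (defaults 0.8 and 1.2).
#' @param nb_size Negative-binomial dispersion (size) for RNA counts
#'   (default 8).
#' @param cnv_fold Planted copy-number fold change (default 1.5).
#' @param seed Mandatory RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cells_per_sample = 750, link_effect_r = 0.7,
                          n_links = 100, doublet_rate = 0.05,
                          low_quality_rate = 0.10,
                          rna_depth_meanlog = log(6000), rna_depth_sdlog = 0.25,
                          atac_depth_meanlog = log(2500), atac_depth_sdlog = 0.25,
                          gamma_rna = 0.8, gamma_atac = 1.2, nb_size = 8,
                          cnv_fold = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells_per_sample >= 40, n_links >= 1, n_links <= 100,
            link_effect_r >= 0, link_effect_r <= 1,
            doublet_rate >= 0, doublet_rate < 0.5,
            low_quality_rate >= 0, low_quality_rate < 0.5)
  structure(list(
    n_cells_per_sample = n_cells_per_sample,
    samples = tibble::tibble(
      sample = c("P1", "P2", "F1", "F2"),
      sex = c("male", "male", "female", "female")
    ),
    cell_types = c("epi_tumor", "macrophage", "fibroblast", "endothelial"),
    type_props = c(epi_tumor = 0.40, macrophage = 0.25,
                   fibroblast = 0.20, endothelial = 0.15),
    link_effect_r = link_effect_r,
    n_links = n_links,
    n_tumor_links = as.integer(ceiling(n_links / 3)),
    doublet_rate = doublet_rate,
    low_quality_rate = low_quality_rate,
    rna_depth_meanlog = rna_depth_meanlog, rna_depth_sdlog = rna_depth_sdlog,
    atac_depth_meanlog = atac_depth_meanlog, atac_depth_sdlog = atac_depth_sdlog,
    gamma_rna = gamma_rna, gamma_atac = gamma_atac, nb_size = nb_size,
    cnv_fold = cnv_fold,
    type_boost = 0.4,
    tile_width = 500L,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Fixed genome layout: coordinates, gene roles, tiles, peaks, planted blocks.
build_genome <- function(cfg) {
  tw <- cfg$tile_width
  chr_len <- 10000000L
  # chr1: 800 genes every 12.5 kb, 100 planted-link blocks of 100 kb
  g1 <- tibble::tibble(
    gene_id = sprintf("G%04d", 1:800),
    chrom = "chr1",
    start = (0:799) * 12500L + 3000L,
    end = (0:799) * 12500L + 5000L,
    strand = rep(c("+", "-"), 400)
  )
  # chr2: 1200 genes every 8 kb
  g2 <- tibble::tibble(
    gene_id = sprintf("G%04d", 801:2000),
    chrom = "chr2",
    start = (0:1199) * 8000L + 3000L,
    end = (0:1199) * 8000L + 5000L,
    strand = rep(c("+", "-"), 600)
  )
  gm <- tibble::tibble(
    gene_id = sprintf("MT-%d", 1:10),
    chrom = "chrM",
    start = (0:9) * 300L,
    end = (0:9) * 300L + 200L,
    strand = "+"
  )
  genes <- gene_models(dplyr::bind_rows(g1, g2, gm))

  tiles <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = chr_len / tw),
    start = rep(seq(0L, chr_len - tw, by = tw), 2)
  )
  tiles$end <- tiles$start + tw
  tiles$id <- paste0(tiles$chrom, ":", tiles$start, "-", tiles$end)

  tile_index <- function(chrom, pos) {
    (pos %/% tw) + 1L + ifelse(chrom == "chr2", chr_len / tw, 0L)
  }

  # planted links: block i (0-based) holds a distal peak after the 5th block
  # gene; targets are block genes 2 and (tumor links) 7
  n_links <- cfg$n_links
  blocks <- 0:(n_links - 1)
  peak_start <- (8L * blocks + 4L) * 12500L + 7500L
  # cell types interleave along the genome (tumor every 3rd block, the
  # lineage types round-robin in between); the coupling latent of each link
  # is a global, cell-type-free factor, cycled over twelve factors so links
  # sharing a factor sit 1.2 Mb apart — far outside the 250-kb candidate
  # window. The link's cell type enters only as a mild accessibility and
  # expression boost, which is what the k-means stage recovers.
  link_type <- character(n_links)
  link_type[blocks %% 3L == 0L] <- "epi_tumor"
  lineage_slots <- which(blocks %% 3L != 0L)
  link_type[lineage_slots] <- rep(c("macrophage", "fibroblast", "endothelial"),
                                  length.out = length(lineage_slots))
  u_index <- blocks %% 4L + 1L
  v_index <- blocks %% 2L + 1L
  target1 <- sprintf("G%04d", 8L * blocks + 2L)
  target2 <- sprintf("G%04d", 8L * blocks + 7L)
  links <- tibble::tibble(
    link = seq_len(n_links),
    peak_id = paste0("chr1:", peak_start, "-", peak_start + tw),
    peak_tile = tile_index("chr1", peak_start),
    celltype = link_type,
    u_index = u_index,
    v_index = v_index,
    target1 = target1,
    target2 = ifelse(link_type == "epi_tumor", target2, NA_character_)
  )

  # chr2 gene roles (indices into genes 801..2000). Role genes are spread
  # evenly along the chromosome instead of clustered: genomically clustered
  # cell-type or latent programs would look exactly like copy-number
  # segments to the genome-ordered smoothing of the CNV stage, whereas an
  # even spread gives every window the same role composition so the
  # per-cell median centering absorbs it.
  chr2_gene <- function(i) sprintf("G%04d", 800L + i)
  free <- rep(TRUE, 1200L)
  take_spread <- function(n) {
    ideal <- round(seq(1, 1200, length.out = n + 2))[2:(n + 1)]
    out <- integer(n)
    for (k in seq_len(n)) {
      j <- ideal[k]
      while (!free[j]) j <- j %% 1200L + 1L
      out[k] <- j
      free[j] <<- FALSE
    }
    sort(out)
  }
  mk_pos <- take_spread(160)
  up_pos <- take_spread(120)
  ua_pos <- take_spread(120)
  vh_pos <- take_spread(40)
  va_pos <- take_spread(40)
  sm_pos <- take_spread(80)
  sex_pos <- take_spread(24)
  fup_pos <- take_spread(15)
  np_pos <- take_spread(48)
  na_pos <- take_spread(48)
  split_cycle <- function(pos, k) lapply(1:k, function(i) {
    chr2_gene(pos[seq(i, length(pos), by = k)])
  })
  cnv_range <- list(P1 = 400:600, P2 = 750:950)
  high_pos <- take_spread(150)
  balancer_pos <- take_spread(200)
  roles <- list(
    markers = stats::setNames(split_cycle(mk_pos, 4),
                              c("epi_tumor", "macrophage", "fibroblast",
                                "endothelial")),
    u_program = split_cycle(up_pos, 4),
    # anti-program hosts close down as their factor rises; they give the
    # accessibility space contrast in both directions and keep each
    # factor's total tile mass nearly flat across cells
    u_anti = split_cycle(ua_pos, 4),
    v_host = split_cycle(vh_pos, 2),
    v_anti = split_cycle(va_pos, 2),
    # nuisance factors: latent programs present in both modalities but
    # never coupled to any planted link; they add honest dimensionality to
    # the manifold so that smooth imputation noise does not concentrate on
    # the few link factors
    nuis_host = split_cycle(np_pos, 4),
    nuis_anti = split_cycle(na_pos, 4),
    sex_male = split_cycle(sex_pos, 2)[[1]],
    sex_female = split_cycle(sex_pos, 2)[[2]],
    sample_markers = stats::setNames(split_cycle(sm_pos, 4),
                                     c("P1", "P2", "F1", "F2")),
    female_up = chr2_gene(fup_pos),
    # a well-expressed housekeeping tier, scattered over both chromosomes:
    # expression-based CNV inference needs genes with enough counts for the
    # fold change to rise above per-window sampling noise
    high_expr = c(sprintf("G%04d", c(8L * 0:98 + 4L, 8L * 1:99)),
                  chr2_gene(high_pos)),
    # copy-number segments are contiguous genomic ranges; balancer genes
    # inside them are left diploid so total-weight balancing stays exact
    cnv = lapply(cnv_range, function(r) {
      chr2_gene(setdiff(r, balancer_pos))
    }),
    balancer = chr2_gene(balancer_pos)
  )

  # latent-program host genes get longer, plus-strand bodies so their
  # program tiles sit well clear of the TSS-enrichment flank window
  host_ids <- c(unlist(roles$u_program), unlist(roles$u_anti),
                unlist(roles$v_host), unlist(roles$v_anti),
                unlist(roles$nuis_host), unlist(roles$nuis_anti))
  hi <- match(host_ids, genes$gene_id)
  genes$end[hi] <- genes$start[hi] + 6000L
  genes$strand[hi] <- "+"
  genes$tss <- NULL
  genes <- gene_models(genes)

  # tiles: promoter (TSS tile), body tiles, program tiles (3 deep-body
  # tiles of each program/host gene)
  nuclear <- genes[genes$chrom != "chrM", , drop = FALSE]
  tss_tile <- tile_index(nuclear$chrom, nuclear$tss)
  body_tiles <- lapply(seq_len(nrow(nuclear)), function(j) {
    tile_index(nuclear$chrom[j],
               seq(nuclear$start[j], nuclear$end[j] - 1L, by = tw))
  })
  names(body_tiles) <- nuclear$gene_id
  tss_tile <- stats::setNames(tss_tile, nuclear$gene_id)
  program_tiles <- function(gene_ids) {
    lapply(gene_ids, function(g) body_tiles[[g]][7:12])
  }
  u_tiles <- lapply(roles$u_program, function(gs) unlist(program_tiles(gs)))
  ua_tiles <- lapply(roles$u_anti, function(gs) unlist(program_tiles(gs)))
  v_tiles <- lapply(roles$v_host, function(gs) unlist(program_tiles(gs)))
  va_tiles <- lapply(roles$v_anti, function(gs) unlist(program_tiles(gs)))
  np_tiles <- lapply(roles$nuis_host, function(gs) unlist(program_tiles(gs)))
  na_tiles <- lapply(roles$nuis_anti, function(gs) unlist(program_tiles(gs)))

  # peak set: planted + 5000 flat decoy distal tiles + 900 promoter tiles.
  # Decoys live only on chromosome 1, whose non-target genes are flat: a
  # decoy near a strongly cell-type-structured gene would otherwise pick up
  # that structure through its finite-sample accessibility offsets.
  free_offsets <- seq(7000L, 13000L, by = tw)
  decoy_pos1 <- as.vector(outer(free_offsets, (0:799) * 12500L, "+"))
  decoy_pos1 <- decoy_pos1[decoy_pos1 + tw <= chr_len]
  decoys <- tibble::tibble(chrom = "chr1", start = sort(decoy_pos1))
  decoys <- decoys[!decoys$start %in% peak_start, ]
  pick <- round(seq(1, nrow(decoys), length.out = min(5000L, nrow(decoys))))
  decoys <- decoys[pick, ]
  prom_genes <- nuclear$gene_id[seq(1, nrow(nuclear), length.out = 900)]
  prom_tile_idx <- tss_tile[prom_genes]
  peaks <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = peak_start, kind = "planted"),
    tibble::tibble(chrom = decoys$chrom, start = decoys$start, kind = "decoy"),
    tibble::tibble(chrom = tiles$chrom[prom_tile_idx],
                   start = tiles$start[prom_tile_idx], kind = "promoter")
  )
  peaks$end <- peaks$start + tw
  peaks$id <- paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  peaks <- peaks[!duplicated(peaks$id), ]
  peaks$tile <- tile_index(peaks$chrom, peaks$start)
  decoy_tiles <- peaks$tile[peaks$kind == "decoy"]

  list(genes = genes, tiles = tiles, links = links, roles = roles,
       peaks = peaks, tss_tile = tss_tile, body_tiles = body_tiles,
       u_tiles = u_tiles, ua_tiles = ua_tiles, v_tiles = v_tiles,
       va_tiles = va_tiles, np_tiles = np_tiles, na_tiles = na_tiles,
       decoy_tiles = decoy_tiles,
       n_tiles = nrow(tiles), tile_index = tile_index)
}

# per-cell metadata for one modality. The chromatin modality exists only
# for the two male patients (the female comparator cohort is
# expression-only), with twice the cells per sample so both modalities have
# about the same total cell count.
draw_cells <- function(cfg, modality) {
  n <- cfg$n_cells_per_sample
  samples <- cfg$samples
  if (modality == "atac") {
    samples <- samples[samples$sex == "male", , drop = FALSE]
    n <- 2L * n
  }
  rows <- lapply(seq_len(nrow(samples)), function(si) {
    smp <- samples$sample[si]
    types <- rep(names(cfg$type_props), round(cfg$type_props * n))
    types <- types[seq_len(n)]
    if (length(types) < n) types <- c(types, rep("epi_tumor", n - length(types)))
    tibble::tibble(
      barcode = sprintf("%s-%s-%04d", smp, toupper(modality), seq_len(n)),
      sample = smp, sex = samples$sex[si],
      cell_type = sample(types)
    )
  })
  cells <- dplyr::bind_rows(rows)
  ntot <- nrow(cells)
  n_lowq <- round(cfg$low_quality_rate * ntot)
  n_dbl <- round(cfg$doublet_rate * ntot)
  flags <- rep("ok", ntot)
  pick <- sample.int(ntot, n_lowq + n_dbl)
  flags[pick[seq_len(n_lowq)]] <- "low_quality"
  if (n_dbl > 0) flags[pick[n_lowq + seq_len(n_dbl)]] <- "doublet"
  cells$is_low_quality <- flags == "low_quality"
  cells$is_doublet <- flags == "doublet"
  # doublet partners: a cell of a different type from the same sample
  cells$partner <- NA_integer_
  for (i in which(cells$is_doublet)) {
    pool <- which(cells$sample == cells$sample[i] &
                    cells$cell_type != cells$cell_type[i] &
                    !cells$is_doublet & !cells$is_low_quality)
    cells$partner[i] <- pool[sample.int(length(pool), 1)]
  }
  cells
}

draw_latents <- function(cfg, cells) {
  n <- nrow(cells)
  # clamped at +/- 2 so the log-linear rate model has bounded tails (a
  # single extreme cell would otherwise dominate the total-weight balancing)
  U <- matrix(pmin(pmax(stats::rnorm(n * 4), -2), 2), n, 4)
  V <- matrix(pmin(pmax(stats::rnorm(n * 2), -2), 2), n, 2)
  N <- matrix(pmin(pmax(stats::rnorm(n * 4), -2), 2), n, 4)
  # doublets mix their two parents' latents
  for (i in which(cells$is_doublet)) {
    j <- cells$partner[i]
    U[i, ] <- (U[i, ] + U[j, ]) / 2
    V[i, ] <- (V[i, ] + V[j, ]) / 2
    N[i, ] <- (N[i, ] + N[j, ]) / 2
  }
  list(U = U, V = V, N = N)
}

# the male-upregulated DE contrast is planted on the tumor links' first
# targets; the chromatin modality is male-only, so the female-side scaling
# cannot touch the metacell correlations
male_up_targets <- function(genome) {
  genome$links$target1[genome$links$celltype == "epi_tumor"]
}

# cells x genes expected-proportion weights for RNA (dense)
rna_weights <- function(cfg, cells, lat, genome) {
  genes <- genome$genes
  n <- nrow(cells)
  gids <- genes$gene_id
  wt <- matrix(1, n, length(gids), dimnames = list(cells$barcode, gids))
  col <- function(ids) match(ids, gids)
  # cell-type markers
  for (tp in names(genome$roles$markers)) {
    j <- col(genome$roles$markers[[tp]])
    at <- cells$cell_type == tp
    wt[at, j] <- 6
    wt[!at, j] <- 0.1
  }
  # latent-program genes and link target genes track their global factor;
  # targets additionally get a mild boost in the link's cell type
  for (g in 1:4) {
    j <- col(genome$roles$u_program[[g]])
    wt[, j] <- 2.5 * exp(cfg$gamma_rna * lat$U[, g])
    jn <- col(genome$roles$nuis_host[[g]])
    wt[, jn] <- 2.5 * exp(cfg$gamma_rna * lat$N[, g])
  }
  lk <- genome$links
  for (l in seq_len(nrow(lk))) {
    boost <- cfg$type_boost * (cells$cell_type == lk$celltype[l])
    # the target slope is kept below the program-gene slope so that the
    # genome-ordered windows over the target-dense chromosome stay inside
    # the CNV denoising band (Pearson correlation is scale-free, so link
    # recovery is unaffected)
    v <- 5 * exp(0.5 * cfg$gamma_rna * lat$U[, lk$u_index[l]] + boost)
    wt[, col(lk$target1[l])] <- v
    if (!is.na(lk$target2[l])) wt[, col(lk$target2[l])] <- v
  }
  # well-expressed housekeeping tier
  wt[, col(genome$roles$high_expr)] <- 4
  # sex-specific hard zeros
  wt[, col(genome$roles$sex_male)] <- ifelse(cells$sex == "male", 2, 0)
  wt[, col(genome$roles$sex_female)] <- ifelse(cells$sex == "female", 2, 0)
  # patient-specific tumor programs
  for (smp in names(genome$roles$sample_markers)) {
    j <- col(genome$roles$sample_markers[[smp]])
    at <- cells$sample == smp & cells$cell_type == "epi_tumor"
    wt[at, j] <- 3
  }
  # male-vs-female DE: first target of each tumor link is male-upregulated,
  # the female_up genes are female-upregulated (in malignant cells)
  # effect sizes are chosen so the planted genes clear the conventional
  # marker-test detection filters (min.pct / min.diff.pct): the contrast
  # must change the detection fraction, not just the mean level
  fem_epi <- cells$sex == "female" & cells$cell_type == "epi_tumor"
  up_genes <- male_up_targets(genome)
  wt[fem_epi, col(up_genes)] <- wt[fem_epi, col(up_genes)] * 0.08
  wt[, col(genome$roles$female_up)] <- 0.5
  wt[fem_epi, col(genome$roles$female_up)] <- 6
  # planted CNV: fold change on segment genes in that patient's tumor cells
  for (smp in names(genome$roles$cnv)) {
    j <- col(genome$roles$cnv[[smp]])
    at <- cells$sample == smp & cells$cell_type == "epi_tumor"
    wt[at, j] <- wt[at, j] * cfg$cnv_fold
  }
  # low-quality cells: flat ambient profile (sex-specific hard zeros are
  # preserved even there)
  wt[cells$is_low_quality, ] <- 1
  wt[cells$sex == "female", col(genome$roles$sex_male)] <- 0
  wt[cells$sex == "male", col(genome$roles$sex_female)] <- 0
  # balancer genes absorb per-cell total-weight differences so that depth
  # normalization induces no cell-type- or state-dependent shift in
  # unrelated genes (which metacell averaging would otherwise turn into
  # spurious correlations)
  mito <- startsWith(gids, "MT-")
  bal_j <- col(genome$roles$balancer)
  rest_j <- setdiff(which(!mito), bal_j)
  t_rest <- rowSums(wt[, rest_j, drop = FALSE])
  nb <- length(bal_j)
  wt[, bal_j] <- matrix((max(t_rest) - t_rest + nb) / nb, n, nb)
  # doublets average their parents (parents' rows are already final)
  for (i in which(cells$is_doublet)) {
    wt[i, ] <- (wt[i, ] + wt[cells$partner[i], ]) / 2
  }
  # mitochondrial load controls pct_mito
  pct <- numeric(n)
  good <- !cells$is_low_quality
  pct[good] <- pmin(pmax(stats::rbeta(sum(good), 2, 38) * 100, 0.5), 20)
  pct[!good] <- stats::runif(sum(!good), 30, 60)
  tot <- rowSums(wt[, !mito, drop = FALSE])
  wt[, mito] <- tot * (pct / 100) / (1 - pct / 100) / sum(mito)
  wt
}

sample_rna <- function(cfg, cells, wt) {
  n <- nrow(cells)
  depth <- round(stats::rlnorm(n, cfg$rna_depth_meanlog, cfg$rna_depth_sdlog))
  depth <- pmax(depth, 2500)
  bad <- cells$is_low_quality
  depth[bad] <- pmin(round(stats::rlnorm(sum(bad), log(800), 0.25)), 1600)
  depth[cells$is_doublet] <- round(depth[cells$is_doublet] * 1.4)
  mu <- wt * (depth / rowSums(wt))
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = cfg$nb_size),
    nrow = n, dimnames = dimnames(wt)
  )
  methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

# static (per cell type) tile weights for ATAC
atac_static_weights <- function(cfg, genome) {
  base <- rep(0.005, genome$n_tiles)
  nuclear <- genome$genes[genome$genes$chrom != "chrM", ]
  for (g in nuclear$gene_id) base[genome$body_tiles[[g]]] <- 0.05
  base[genome$tss_tile] <- 10
  # latent-program host promoters are kept weak so their gene-activity
  # scores are dominated by the latent-driven body tiles
  host_ids <- c(unlist(genome$roles$u_program), unlist(genome$roles$u_anti),
                unlist(genome$roles$v_host), unlist(genome$roles$v_anti))
  base[genome$tss_tile[host_ids]] <- 2
  base[genome$decoy_tiles] <- 1
  per_type <- lapply(names(cfg$type_props), function(tp) {
    w <- base
    for (g in genome$roles$markers[[tp]]) {
      w[genome$body_tiles[[g]]] <- w[genome$body_tiles[[g]]] * 3
      w[genome$tss_tile[g]] <- w[genome$tss_tile[g]] * 3
    }
    w
  })
  names(per_type) <- names(cfg$type_props)
  per_type
}

sample_atac <- function(cfg, cells, lat, genome) {
  n <- nrow(cells)
  tw_static <- atac_static_weights(cfg, genome)
  static_cum <- lapply(tw_static, cumsum)
  static_tot <- vapply(static_cum, function(x) x[length(x)], 0)
  uniform_cum <- cumsum(rep(1, genome$n_tiles))
  # internal mixing is calibrated so that the EMPIRICAL metacell-level
  # correlation approaches link_effect_r: the measurement pipeline
  # (imputation, aggregation, counting noise) attenuates the latent
  # correlation by a measured factor of roughly 0.85-0.95 (pilot runs; the
  # calibration uses the lower bound so per-link attenuation variability
  # does not push links below their nominal effect), which the
  # mixing coefficient compensates for
  alpha <- min(1, cfg$link_effect_r / 0.85)
  beta <- sqrt(1 - alpha^2)
  # dynamic tiles: latent-program tiles and planted peaks
  dyn_idx <- c(unlist(genome$u_tiles), unlist(genome$ua_tiles),
               unlist(genome$v_tiles), unlist(genome$va_tiles),
               unlist(genome$np_tiles), unlist(genome$na_tiles),
               genome$links$peak_tile)
  u_rep <- rep(1:4, times = lengths(genome$u_tiles))
  ua_rep <- rep(1:4, times = lengths(genome$ua_tiles))
  v_rep <- rep(1:2, times = lengths(genome$v_tiles))
  va_rep <- rep(1:2, times = lengths(genome$va_tiles))
  np_rep <- rep(1:4, times = lengths(genome$np_tiles))
  na_rep <- rep(1:4, times = lengths(genome$na_tiles))
  link_boost <- outer(cells$cell_type, genome$links$celltype, "==") *
    cfg$type_boost
  depth <- round(stats::rlnorm(n, cfg$atac_depth_meanlog, cfg$atac_depth_sdlog))
  depth <- pmax(depth, 1200)
  bad <- cells$is_low_quality
  depth[bad] <- pmin(round(stats::rlnorm(sum(bad), log(300), 0.3)), 800)
  depth[cells$is_doublet] <- round(depth[cells$is_doublet] * 1.4)

  dyn_values <- function(i) {
    a_link <- alpha * lat$U[cbind(i, genome$links$u_index)] +
      beta * lat$V[cbind(i, genome$links$v_index)]
    c(3 * exp(1.2 * pmin(pmax(lat$U[i, u_rep], -1.5), 1.5)),
      3 * exp(-1.2 * pmin(pmax(lat$U[i, ua_rep], -1.5), 1.5)),
      1.5 * exp(1.2 * pmin(pmax(lat$V[i, v_rep], -1.5), 1.5)),
      1.5 * exp(-1.2 * pmin(pmax(lat$V[i, va_rep], -1.5), 1.5)),
      3 * exp(1.2 * pmin(pmax(lat$N[i, np_rep], -1.5), 1.5)),
      3 * exp(-1.2 * pmin(pmax(lat$N[i, na_rep], -1.5), 1.5)),
      3 * exp(cfg$gamma_atac * a_link + link_boost[i, ]))
  }
  # per-cell uniform background mass absorbs total-weight differences so
  # that every sound cell has the same expected total accessibility weight;
  # without this, depth normalization imprints latent- and type-dependent
  # shifts on every flat tile, which metacell averaging would turn into
  # spurious peak-gene correlations
  dyn_tot <- vapply(seq_len(n), function(i) sum(dyn_values(i)), 0)
  grand_tot <- stats::quantile(static_tot[cells$cell_type] + dyn_tot, 0.995,
                               names = FALSE) + 800
  draw_cell <- function(i, d) {
    if (cells$is_low_quality[i]) {
      u <- stats::runif(d) * genome$n_tiles
      return(findInterval(u, uniform_cum) + 1L)
    }
    cum <- static_cum[[cells$cell_type[i]]]
    dv <- dyn_values(i)
    wd <- sum(dv)
    ws <- static_tot[[cells$cell_type[i]]]
    wb <- max(grand_tot - ws - wd, 100)
    nb <- stats::rbinom(1, d, wb / (ws + wd + wb))
    nd <- stats::rbinom(1, d - nb, wd / (ws + wd))
    bg <- findInterval(stats::runif(nb) * genome$n_tiles, uniform_cum) + 1L
    st <- findInterval(stats::runif(d - nb - nd) * ws, cum) + 1L
    dyn <- dyn_idx[findInterval(stats::runif(nd) * wd, cumsum(dv)) + 1L]
    c(bg, st, dyn)
  }
  ti <- vector("list", n)
  for (i in seq_len(n)) {
    if (cells$is_doublet[i]) {
      j <- cells$partner[i]
      d1 <- stats::rbinom(1, depth[i], 0.5)
      idx <- c(draw_cell(i, d1), draw_cell(j, depth[i] - d1))
    } else {
      idx <- draw_cell(i, depth[i])
    }
    tb <- tabulate(idx, genome$n_tiles)
    nzi <- which(tb > 0)
    ti[[i]] <- cbind(i, nzi, tb[nzi])
  }
  trip <- do.call(rbind, ti)
  out <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                              dims = c(n, genome$n_tiles),
                              dimnames = list(cells$barcode, genome$tiles$id))
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Generate a synthetic matched scRNA/scATAC cohort with planted truth
#'
#' @param cfg A `cohort_config`.
#' @return A `synthetic_cohort`: list with `rna` and `atac` (cells x features
#'   sparse counts), `genes` (gene models), `tiles` and `peaks` (interval
#'   tibbles), `reference_enhancers` (a synthetic stand-in for a normal
#'   epithelium enhancer BED that covers the lineage planted peaks but no
#'   tumor planted peak), `marker_sets`, and `truth` (cell table, planted
#'   links, CNV segments, DE genes, sex genes).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::local_seed(cfg$seed)
  genome <- build_genome(cfg)
  rna_cells <- draw_cells(cfg, "rna")
  atac_cells <- draw_cells(cfg, "atac")
  rna_lat <- draw_latents(cfg, rna_cells)
  atac_lat <- draw_latents(cfg, atac_cells)
  rna <- sample_rna(cfg, rna_cells, rna_weights(cfg, rna_cells, rna_lat, genome))
  atac <- sample_atac(cfg, atac_cells, atac_lat, genome)

  peaks <- genomic_intervals(genome$peaks[, c("chrom", "start", "end", "id")])
  lk <- genome$links
  planted_links <- dplyr::bind_rows(
    tibble::tibble(peak_id = lk$peak_id, gene_id = lk$target1,
                   celltype = lk$celltype,
                   target_metacell_r = cfg$link_effect_r),
    tibble::tibble(peak_id = lk$peak_id[!is.na(lk$target2)],
                   gene_id = lk$target2[!is.na(lk$target2)],
                   celltype = lk$celltype[!is.na(lk$target2)],
                   target_metacell_r = cfg$link_effect_r)
  ) |> dplyr::arrange(.data$peak_id, .data$gene_id)

  seg_bounds <- function(ids) {
    g <- genome$genes[match(ids, genome$genes$gene_id), ]
    c(min(g$start), max(g$end))
  }
  cnv_segments <- dplyr::bind_rows(lapply(names(genome$roles$cnv), function(smp) {
    b <- seg_bounds(genome$roles$cnv[[smp]])
    tibble::tibble(sample = smp, chrom = "chr2", start = b[1], end = b[2],
                   fold = cfg$cnv_fold,
                   n_genes = length(genome$roles$cnv[[smp]]))
  }))
  de_genes <- dplyr::bind_rows(
    tibble::tibble(gene_id = male_up_targets(genome),
                   direction = "up", planted_log2fc = 3.6),
    tibble::tibble(gene_id = genome$roles$sex_male, direction = "up",
                   planted_log2fc = Inf),
    tibble::tibble(gene_id = genome$roles$female_up, direction = "down",
                   planted_log2fc = -2),
    tibble::tibble(gene_id = genome$roles$sex_female, direction = "down",
                   planted_log2fc = -Inf)
  )

  # synthetic normal-epithelium reference enhancers: exactly the lineage
  # planted peaks plus a sample of decoy intervals; never a tumor planted
  # peak
  lineage_peaks <- peaks[peaks$id %in% lk$peak_id[lk$celltype != "epi_tumor"], ]
  decoy_rows <- genome$peaks[genome$peaks$kind == "decoy", ]
  decoy_sample <- decoy_rows[round(seq(1, nrow(decoy_rows), length.out = 500)), ]
  reference_enhancers <- genomic_intervals(dplyr::bind_rows(
    lineage_peaks[, c("chrom", "start", "end")],
    decoy_sample[, c("chrom", "start", "end")]
  ))

  truth <- list(
    latents = list(rna = rna_lat, atac = atac_lat),
    cell_table = dplyr::bind_rows(
      dplyr::mutate(rna_cells, modality = "rna"),
      dplyr::mutate(atac_cells, modality = "atac")
    ) |> dplyr::select(-"partner"),
    planted_links = planted_links,
    tumor_peak_ids = lk$peak_id[lk$celltype == "epi_tumor"],
    lineage_peak_ids = lk$peak_id[lk$celltype != "epi_tumor"],
    cnv_segments = cnv_segments,
    cnv_genes = genome$roles$cnv,
    de_genes = de_genes,
    sex_genes = list(male_only = genome$roles$sex_male,
                     female_only = genome$roles$sex_female)
  )
  structure(list(
    rna = rna, atac = atac,
    genes = genome$genes, tiles = genomic_intervals(genome$tiles),
    peaks = peaks, reference_enhancers = reference_enhancers,
    marker_sets = genome$roles$markers,
    truth = truth, config = cfg
  ), class = "synthetic_cohort")
}

#' @noRd
#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d RNA cells x %d genes; %d ATAC cells x %d tiles; %d peaks; %d planted links\n",
              nrow(x$rna), ncol(x$rna), nrow(x$atac), ncol(x$atac),
              nrow(x$peaks), nrow(x$truth$planted_links)))
  invisible(x)
}

#' Write a cohort to disk as plain-text fixture files
#'
#' Emits CellRanger-style MTX directories for both modalities, BED files for
#' peaks and reference enhancers, the gene-model TSV, the marker-set GMT and
#' the ground-truth tables.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory; must be empty unless `force = TRUE`.
#' @param force Overwrite a non-empty directory?
#' @return `dir`, invisibly.
#' @export
emit_fixture <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(cohort$rna, file.path(dir, "rna"))
  write_counts_mtx(cohort$atac, file.path(dir, "atac"))
  write_bed(cohort$peaks, file.path(dir, "peaks.bed"))
  write_bed(cohort$reference_enhancers, file.path(dir, "reference_enhancers.bed"))
  write_gene_models(cohort$genes, file.path(dir, "genes.tsv"))
  write_gmt(cohort$marker_sets, file.path(dir, "marker_sets.gmt"))
  readr::write_tsv(cohort$truth$cell_table, file.path(dir, "truth_cells.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$planted_links, file.path(dir, "truth_links.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$cnv_segments, file.path(dir, "truth_cnv.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$de_genes, file.path(dir, "truth_de.tsv"),
                   progress = FALSE)
  invisible(dir)
}
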