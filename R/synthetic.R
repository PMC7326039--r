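#' Sampling plan for a synthetic cohort
#'
#' Defaults emulate a 58-tumor bladder-cancer cohort: 17 G1, 5 G2 and 36 G3
#' samples (30 NMIBC G3 plus 6 MIBC, all G3), with desk-scale sequencing
#' depth. Library sizes are drawn log-normally around `mean_library_size`.
#'
#' @param n_per_grade Named integer vector of samples per grade.
#' @param n_mibc Number of muscle-invasive samples; they are taken from the
#'   G3 stratum.
#' @param mean_library_size Mean total mapped reads per sample. CPM
#'   normalization makes downstream results scale-free, so a depth in the
#'   1e5-1e6 range stands in for production-scale libraries.
#' @param library_size_cv Log-scale standard deviation of library sizes.
#' @return A list of class `circ_sample_plan`.
#' @export
sample_plan <- function(n_per_grade = c(G1 = 17, G2 = 5, G3 = 36),
                        n_mibc = 6, mean_library_size = 2e5,
                        library_size_cv = 0.1) {
  if (any(n_per_grade < 0) || sum(n_per_grade) < 1) {
    abort("sample plan must contain at least one sample")
  }
  if (n_mibc > n_per_grade[["G3"]]) abort("n_mibc cannot exceed the G3 count")
  structure(list(n_per_grade = n_per_grade, n_mibc = n_mibc,
                 mean_library_size = mean_library_size,
                 library_size_cv = library_size_cv),
            class = "circ_sample_plan")
}

#' Grade-effect spike configuration
#'
#' Designates a subset of junctions whose circular-to-linear log-ratio is
#' shifted by `effect_size` log2 units in the designated grades (the circular
#' mean is scaled by `2^(direction * effect_size)` there; the linear mean is
#' untouched, so the differential-relative-expression ground truth is
#' unambiguous).
#'
#' @param n_spiked Number of junctions with grade-dependent relative
#'   expression.
#' @param effect_size Additive shift in log2 units, `>= 0`.
#' @param prop_up Fraction of spiked junctions shifted up (the rest down).
#' @param grades Grades in which the shift applies.
#' @return A list of class `circ_spike_config`.
#' @export
spike_config <- function(n_spiked = 100, effect_size = 1, prop_up = 0.5,
                         grades = "G3") {
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (n_spiked < 0) abort("n_spiked must be >= 0")
  structure(list(n_spiked = as.integer(n_spiked), effect_size = effect_size,
                 prop_up = prop_up, grades = grades),
            class = "circ_spike_config")
}

#' Generate a synthetic annotation database
#'
#' Lays non-overlapping gene models on `chrom_count` chromosomes. Each gene
#' receives exons separated by introns, and its exonic space is partitioned
#' in transcription order into a 5'UTR (~15%), CDS (~70%) and 3'UTR (~15%).
#' Deterministic given `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene_range Inclusive range to draw exon counts from.
#' @param chrom_count Number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length Chromosome length in bases; exceeding it while packing
#'   genes is a configuration error.
#' @param seed Integer RNG seed.
#' @return A [annotation_db()] object.
#' @export
generate_annotation <- function(n_genes = 200, exons_per_gene_range = c(3, 8),
                                chrom_count = 4, chrom_length = 5e6, seed = 1) {
  if (n_genes < 1) abort("n_genes must be >= 1 (configuration error)")
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(chrom_count))
    cursor <- setNames(rep(0L, chrom_count), chroms)
    genes <- vector("list", n_genes)
    feats <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      chrom <- chroms[((i - 1L) %% chrom_count) + 1L]
      n_ex <- sample(seq(exons_per_gene_range[1], exons_per_gene_range[2]), 1)
      ex_len <- sample(120:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(300:2000, n_ex - 1, replace = TRUE) else integer(0)
      gap <- sample(5000:20000, 1)
      g_start <- cursor[[chrom]] + gap
      ex_start <- g_start + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len
      g_end <- ex_end[n_ex]
      if (g_end > chrom_length) {
        abort("infeasible packing: genes exceed chromosome length (configuration error)")
      }
      cursor[[chrom]] <- g_end
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("G%04d", i)
      genes[[i]] <- tibble(gene_id = gid, gene_name = paste0("GENE", i),
                           chrom = chrom, start = g_start, end = g_end,
                           strand = strand)
      # partition exonic bases into UTR5 / CDS / UTR3 in transcription order
      lx <- sum(ex_len)
      u5 <- max(1L, round(0.15 * lx)); u3 <- max(1L, round(0.15 * lx))
      # genomic-order region lengths (5'UTR is leftmost on +, rightmost on -)
      seg_len <- if (strand == "+") c(u5, lx - u5 - u3, u3) else c(u3, lx - u5 - u3, u5)
      seg_lab <- if (strand == "+") c("utr5", "cds", "utr3") else c("utr3", "cds", "utr5")
      bnd <- cumsum(seg_len)
      pieces <- list()
      off <- 0L
      for (e in seq_len(n_ex)) {
        lo <- off; hi <- off + ex_len[e]
        for (s in seq_along(seg_len)) {
          s_lo <- c(0L, bnd)[s]; s_hi <- bnd[s]
          p_lo <- max(lo, s_lo); p_hi <- min(hi, s_hi)
          if (p_hi > p_lo) {
            pieces[[length(pieces) + 1L]] <- tibble(
              gene_id = gid, chrom = chrom,
              start = ex_start[e] + (p_lo - lo), end = ex_start[e] + (p_hi - lo),
              strand = strand, region = seg_lab[s])
          }
        }
        off <- hi
      }
      feats[[i]] <- list(
        exons = tibble(gene_id = gid, chrom = chrom, start = ex_start,
                       end = ex_end, strand = strand,
                       exon_rank = if (identical(strand[1], "+")) seq_len(n_ex) else rev(seq_len(n_ex))),
        regions = bind_rows(pieces))
    }
    regions <- bind_rows(map(feats, "regions"))
    annotation_db(
      genes = bind_rows(genes),
      exons = bind_rows(map(feats, "exons")),
      cds = regions |> filter(.data$region == "cds") |> select(-"region"),
      utr5 = regions |> filter(.data$region == "utr5") |> select(-"region"),
      utr3 = regions |> filter(.data$region == "utr3") |> select(-"region")
    )
  })
}

# sample positions for one synthetic junction per context class
place_junctions <- function(annotation, n, context) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (context == "exonic") {
    ex_by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
    gid <- sample(names(ex_by_gene), n, replace = TRUE)
    res <- map(gid, function(g) {
      idx <- ex_by_gene[[g]]
      ij <- sort(sample(idx, min(2, length(idx)), replace = length(idx) == 1))
      e1 <- exons[ij[1], ]; e2 <- exons[ij[length(ij)], ]
      s <- e1$start + sample.int(e1$end - e1$start, 1) - 1L
      e <- e2$start + sample.int(e2$end - e2$start, 1)
      if (e <= s + 1L) { s <- e1$start; e <- e2$end }
      tibble(chrom = e1$chrom, start = s, end = e,
             strand = e1$strand, host_gene = g)
    })
    bind_rows(res)
  } else if (context == "intronic") {
    multi <- genes$gene_id[genes$gene_id %in%
                             (exons |> count(.data$gene_id) |> filter(n > 1) |> pull("gene_id"))]
    if (length(multi) == 0) abort("no multi-exon genes available for intronic junctions")
    gid <- sample(multi, n, replace = TRUE)
    res <- map(gid, function(g) {
      ex <- exons |> filter(.data$gene_id == g) |> arrange(.data$start)
      k <- sample.int(nrow(ex) - 1, 1)
      lo <- ex$end[k]; hi <- ex$start[k + 1]
      pos <- sort(sample(seq(lo, hi - 1L), 2))
      tibble(chrom = ex$chrom[1], start = pos[1], end = pos[2] + 1L,
             strand = ex$strand[1], host_gene = g)
    })
    bind_rows(res)
  } else {
    gaps <- genes |> group_by(.data$chrom) |> arrange(.data$start, .by_group = TRUE) |>
      summarise(gap_start = list(.data$end[-n()] + 50L),
                gap_end = list(.data$start[-1] - 50L), .groups = "drop") |>
      unnest(c("gap_start", "gap_end")) |>
      filter(.data$gap_end - .data$gap_start > 200L)
    if (nrow(gaps) == 0) abort("no intergenic space available")
    gi <- sample.int(nrow(gaps), n, replace = TRUE)
    res <- map(gi, function(i) {
      g <- gaps[i, ]
      pos <- sort(sample(seq(g$gap_start, g$gap_end - 1L), 2))
      tibble(chrom = g$chrom, start = pos[1], end = pos[2] + 1L,
             strand = sample(c("+", "-"), 1), host_gene = NA_character_)
    })
    bind_rows(res)
  }
}

#' Generate a synthetic circRNA cohort with known ground truth
#'
#' Produces, deterministically given `seed`: the sample table, a set of
#' back-splice junctions with a configurable genomic-context mix (default
#' 94% exonic / 4% intronic / 2% intergenic), per-sample circular read
#' counts, linear splice counts at every junction boundary, optional
#' read-level chimeric records, and a truth table for the spiked junctions.
#'
#' Counts follow a negative binomial around a per-junction baseline (mean
#' scaled by each sample's library size); circular and linear counts are
#' drawn independently with a common dispersion. Spiked junctions have their
#' circular mean multiplied by `2^(direction * effect_size)` in the
#' designated grades.
#'
#' @param annotation A `circ_annotation`, e.g. from [generate_annotation()].
#' @param n_junctions Total junctions to simulate.
#' @param spike A [spike_config()].
#' @param plan A [sample_plan()].
#' @param context_mix Named proportions for exonic/intronic/intergenic.
#' @param dispersion Negative-binomial dispersion (edgeR-style; variance
#'   `mu + dispersion * mu^2`). `0` gives Poisson counts.
#' @param circ_baseline,lin_baseline Named vectors `c(meanlog=, sdlog=)` for
#'   the log-normal baseline mean counts at the plan's mean library size.
#' @param include_chimeric Emit one chimeric record per supporting read
#'   (memory scales with total read count; disable for large statistical
#'   simulations that start from counts).
#' @param seed Integer RNG seed governing the cohort structure (samples,
#'   junction placement, baselines, spike assignment).
#' @param count_seed Seed for the count draws; defaults to `seed`. Two calls
#'   differing only in `count_seed` share the same junctions, baselines and
#'   spike truth — independent replicate cohorts from one ground truth.
#' @return A list of class `circ_cohort` with elements `samples`,
#'   `junctions`, `circ_counts` (long), `linear` (boundary counts, long),
#'   `chimeric` (tibble or NULL) and `truth`.
#' @export
generate_cohort <- function(annotation, n_junctions = 2000,
                            spike = spike_config(), plan = sample_plan(),
                            context_mix = c(exonic = 0.94, intronic = 0.04,
                                            intergenic = 0.02),
                            dispersion = 0.3,
                            circ_baseline = c(meanlog = log(15), sdlog = 0.7),
                            lin_baseline = c(meanlog = log(150), sdlog = 0.7),
                            include_chimeric = TRUE, seed = 1,
                            count_seed = seed) {
  if (spike$n_spiked > n_junctions) {
    abort("n_spiked exceeds n_junctions (configuration error)")
  }
  design <- withr::with_seed(seed, {
    ## --- samples ---------------------------------------------------------
    grades <- rep(names(plan$n_per_grade), plan$n_per_grade)
    n_s <- length(grades)
    stage <- rep("NMIBC", n_s)
    g3 <- which(grades == "G3")
    if (plan$n_mibc > 0) stage[utils::tail(g3, plan$n_mibc)] <- "MIBC"
    samples <- tibble(sample_id = sprintf("S%02d", seq_len(n_s)),
                      grade = grades, stage_class = stage)

    ## --- junctions -------------------------------------------------------
    n_ctx <- round(context_mix * n_junctions)
    n_ctx["exonic"] <- n_junctions - sum(n_ctx[c("intronic", "intergenic")])
    jx <- bind_rows(imap(n_ctx[n_ctx > 0],
                         function(n, ctx) place_junctions(annotation, n, ctx) |>
                           mutate(context = ctx)))
    for (it in 1:25) {
      key <- junction_key(jx$chrom, jx$start, jx$end, jx$strand)
      dup <- duplicated(key)
      if (!any(dup)) break
      redo <- bind_rows(imap(split(seq_len(nrow(jx))[dup], jx$context[dup]),
                             function(i, ctx) place_junctions(annotation, length(i), ctx) |>
                               mutate(context = ctx)))
      jx[dup, ] <- redo[, names(jx)]
    }
    if (anyDuplicated(junction_key(jx$chrom, jx$start, jx$end, jx$strand))) {
      abort("could not place distinct junctions; enlarge the annotation")
    }
    jx <- jx |>
      mutate(junction_id = junction_key(.data$chrom, .data$start, .data$end,
                                        .data$strand)) |>
      arrange(.data$chrom, .data$start, .data$end) |>
      select("junction_id", "chrom", "start", "end", "strand", "context",
             "host_gene")

    ## --- spike and baselines --------------------------------------------
    n_j <- nrow(jx)
    circ_mu <- rlnorm(n_j, circ_baseline[["meanlog"]], circ_baseline[["sdlog"]])
    spiked_idx <- if (spike$n_spiked > 0) sample.int(n_j, spike$n_spiked) else integer(0)
    direction <- integer(n_j)
    if (length(spiked_idx) > 0) {
      n_up <- round(spike$prop_up * length(spiked_idx))
      direction[spiked_idx] <- sample(rep(c(1L, -1L),
                                          c(n_up, length(spiked_idx) - n_up)))
    }

    ## --- boundary linear means ------------------------------------------
    bounds <- bind_rows(
      jx |> select("chrom", pos = "start"),
      jx |> select("chrom", pos = "end")
    ) |> distinct()
    bounds$lin_mu <- rlnorm(nrow(bounds), lin_baseline[["meanlog"]],
                            lin_baseline[["sdlog"]])
    list(samples = samples, jx = jx, circ_mu = circ_mu,
         spiked_idx = spiked_idx, direction = direction, bounds = bounds,
         grades = grades, n_j = n_j, n_s = n_s)
  })

  samples <- design$samples; jx <- design$jx; circ_mu <- design$circ_mu
  spiked_idx <- design$spiked_idx; direction <- design$direction
  bounds <- design$bounds; grades <- design$grades
  n_j <- design$n_j; n_s <- design$n_s

  withr::with_seed(count_seed, {
    ## --- library sizes and counts ---------------------------------------
    # libraries belong to the sampled patients, so replicate cohorts
    # (same seed, new count_seed) draw fresh ones
    lib <- as.integer(round(rlnorm(n_s, log(plan$mean_library_size),
                                   plan$library_size_cv)))
    samples$library_size <- lib
    scale_s <- lib / plan$mean_library_size
    in_designated <- grades %in% spike$grades
    fc <- matrix(1, n_j, n_s)
    if (length(spiked_idx) > 0 && spike$effect_size > 0) {
      fc[spiked_idx, in_designated] <-
        2^(spike$effect_size * direction[spiked_idx])
    }
    mu_c <- outer(circ_mu, scale_s) * fc
    draw <- function(mu) {
      if (dispersion <= 0) stats::rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    C <- matrix(draw(mu_c), n_j, n_s)
    circ_counts <- tibble(
      junction_id = rep(jx$junction_id, times = n_s),
      sample_id = rep(samples$sample_id, each = n_j),
      count = as.integer(C)
    )
    mu_l <- outer(bounds$lin_mu, scale_s)
    L <- matrix(draw(mu_l), nrow(bounds), n_s)
    linear <- tibble(
      sample_id = rep(samples$sample_id, each = nrow(bounds)),
      chrom = rep(bounds$chrom, times = n_s),
      pos = rep(bounds$pos, times = n_s),
      count = as.integer(L)
    )

    ## --- truth -----------------------------------------------------------
    blu <- bounds$lin_mu
    names(blu) <- paste0(bounds$chrom, ":", bounds$pos)
    jx_lin_mu <- pmax(blu[paste0(jx$chrom, ":", jx$start)],
                      blu[paste0(jx$chrom, ":", jx$end)])
    mean_lib <- plan$mean_library_size
    true_mean <- function(g) {
      f <- ifelse(seq_len(n_j) %in% spiked_idx & g %in% spike$grades,
                  2^(spike$effect_size * direction), 1)
      log2(circ_mu * f / mean_lib * 1e6 + 1) - log2(jx_lin_mu / mean_lib * 1e6 + 1)
    }
    truth <- tibble(
      junction_id = jx$junction_id,
      is_spiked = seq_len(n_j) %in% spiked_idx,
      direction = ifelse(direction > 0, "up", ifelse(direction < 0, "down", "none")),
      host_gene = jx$host_gene, context = jx$context,
      true_mean_G1 = true_mean("G1"),
      true_mean_G2 = true_mean("G2"),
      true_mean_G3 = true_mean("G3")
    )

    ## --- chimeric records ------------------------------------------------
    chimeric <- NULL
    if (include_chimeric) {
      nz <- circ_counts |> filter(.data$count > 0) |>
        left_join(jx, by = "junction_id")
      reps <- rep(seq_len(nrow(nz)), nz$count)
      ch <- nz[reps, ]
      plus <- ch$strand == "+"
      chimeric <- tibble(
        sample_id = ch$sample_id,
        chrom_donor = ch$chrom,
        pos_donor = ifelse(plus, ch$end, ch$start),
        strand_donor = ch$strand,
        chrom_acceptor = ch$chrom,
        pos_acceptor = ifelse(plus, ch$start, ch$end),
        strand_acceptor = ch$strand,
        read_id = paste0("read", seq_len(nrow(ch)))
      )
      chimeric <- chimeric[sample.int(nrow(chimeric)), ]
    }

    structure(list(samples = samples, junctions = jx,
                   circ_counts = circ_counts, linear = linear,
                   chimeric = chimeric, truth = truth),
              class = "circ_cohort")
  })
}

#' @export
print.circ_cohort <- function(x, ...) {
  cat("<circ_cohort> ", nrow(x$junctions), " junctions x ", nrow(x$samples),
      " samples (", sum(x$truth$is_spiked), " spiked)\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Serializes the cohort in the package's file dialects: `samples.tsv`,
#' `linear.tsv`, `junctions.bed`, `truth.tsv` and, when present,
#' `chimeric.tsv`. Output bytes are a pure function of the cohort object.
#'
#' @param cohort A `circ_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_linear_table(cohort$linear, file.path(dir, "linear.tsv"))
  write_bed(cohort$junctions |>
              mutate(name = .data$junction_id, score = 0) |>
              select("chrom", "start", "end", "name", "score", "strand"),
            file.path(dir, "junctions.bed"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  if (!is.null(cohort$chimeric)) {
    write_chimeric_table(cohort$chimeric, file.path(dir, "chimeric.tsv"))
  }
  invisible(dir)
}

#' Generate a synthetic miRNA target-site table
#'
#' Sites of length 7 or 8 bp (conserved seed-match lengths), except a
#' `frac_long` fraction of length 9-12; each site is placed inside a
#' simulated gene body. Deterministic given `seed`.
#'
#' @param annotation A `circ_annotation` supplying gene bodies.
#' @param n_sites Number of sites (>= 1).
#' @param frac_long Fraction of sites with length > 8.
#' @param seed Integer RNG seed.
#' @return A site tibble (`chrom`, `start`, `end`, `mirna_family`,
#'   `gene_symbol`, `site_length`).
#' @export
generate_site_table <- function(annotation, n_sites, frac_long = 0, seed = 1) {
  if (n_sites < 1) abort("n_sites must be >= 1 (configuration error)")
  if (frac_long < 0 || frac_long > 1) abort("frac_long must be in [0, 1]")
  withr::with_seed(seed, {
    n_long <- round(frac_long * n_sites)
    len <- c(sample(7:8, n_sites - n_long, replace = TRUE),
             if (n_long > 0) sample(9:12, n_long, replace = TRUE))
    len <- sample(len)
    genes <- annotation$genes
    gi <- sample.int(nrow(genes), n_sites, replace = TRUE)
    width <- genes$end[gi] - genes$start[gi]
    off <- floor(runif(n_sites) * (width - len))
    fam <- sprintf("miR-%d-%s", sample(1:300, n_sites, replace = TRUE),
                   sample(c("5p", "3p"), n_sites, replace = TRUE))
    tibble(chrom = genes$chrom[gi],
           start = genes$start[gi] + as.integer(off),
           end = genes$start[gi] + as.integer(off) + len,
           mirna_family = fam,
           gene_symbol = genes$gene_name[gi],
           site_length = len)
  })
}

#' Generate a reference cohort circRNA list
#'
#' Emulates an externally published circRNA set against which the query
#' cohort is compared: `round(match_fraction * nrow(junctions))` entries copy
#' real junctions (with the start coordinate shifted by `coordinate_offset`
#' to mimic a 1-based convention), and the remaining `n_reference - matched`
#' entries are novel intervals guaranteed not to match. Deterministic given
#' `seed`.
#'
#' @param junctions Junction tibble (`chrom`, `start`, `end`, ...).
#' @param match_fraction Fraction of `junctions` copied into the reference.
#' @param coordinate_offset 0 or +1 added to start coordinates.
#' @param n_reference Total reference size (default `nrow(junctions)`).
#' @param seed Integer RNG seed.
#' @return BED-like tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
generate_reference_cohort <- function(junctions, match_fraction,
                                      coordinate_offset = 0,
                                      n_reference = nrow(junctions), seed = 1) {
  if (nrow(junctions) == 0) abort("empty junction list (configuration error)")
  if (match_fraction < 0 || match_fraction > 1) {
    abort("match_fraction must be in [0, 1]")
  }
  if (!coordinate_offset %in% c(0, 1)) {
    abort("coordinate_offset must be 0 or +1 (configuration error)")
  }
  withr::with_seed(seed, {
    n_match <- round(match_fraction * nrow(junctions))
    if (n_match > n_reference) abort("n_reference smaller than matched count")
    matched <- junctions[sample.int(nrow(junctions), n_match), ] |>
      select("chrom", "start", "end", strand = dplyr::any_of("strand"))
    if (!"strand" %in% names(matched)) matched$strand <- "."
    n_novel <- n_reference - n_match
    novel <- NULL
    if (n_novel > 0) {
      base <- max(junctions$end) + 10000L
      w <- sample(100:2000, n_novel, replace = TRUE)
      st <- base + cumsum(sample(500:5000, n_novel, replace = TRUE))
      novel <- tibble(chrom = sample(unique(junctions$chrom), n_novel,
                                     replace = TRUE),
                      start = st, end = st + w,
                      strand = sample(c("+", "-"), n_novel, replace = TRUE))
    }
    bind_rows(matched, novel) |>
      mutate(start = .data$start + coordinate_offset) |>
      arrange(.data$chrom, .data$start, .data$end) |>
      mutate(name = paste0("ref", row_number()), score = 0) |>
      select("chrom", "start", "end", "name", "score", "strand")
  })
}
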