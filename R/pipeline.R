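#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline. The defaults are the
#' study's design: pool sizes 21/21 (female informative), 26/24 (male
#' informative I) and 26/28 (male informative II); pooled depths 50/60;
#' error-free reads; a 15 vs 15 re-sequencing panel; a 3 kb
#' presence/absence insertion read at baseline depth 30. Any subset of
#' fields can be overridden from a YAML file ([read_run_config()]).
#'
#' @param seed integer run seed; every stage derives its own stream
#'   from it.
#' @param outdir output directory (default: a fresh temporary
#'   directory at run time).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = NULL) {
  structure(
    list(
      seed = as.integer(seed),
      outdir = outdir,
      genome = list(
        n_contigs = 10L, sites_per_contig = 40L, causal_contig = 3L,
        causal_site = 20L, informative_fraction = 0.3, r_causal = 0
      ),
      crosses = list(
        female_informative = list(
          n_alba_offspring = 21L, n_orange_offspring = 21L,
          pool_depth_mean = 50, mother_depth_mean = 40, seq_error = 0
        ),
        male_informative_I = list(
          n_alba_offspring = 26L, n_orange_offspring = 24L,
          pool_depth_mean = 60, mother_depth_mean = 15, seq_error = 0
        ),
        male_informative_II = list(
          n_alba_offspring = 26L, n_orange_offspring = 28L,
          pool_depth_mean = 60, seq_error = 0
        )
      ),
      bsa = list(hom_tol = 0, min_snps = 3L, indel_mask_window = 5L),
      panel = list(
        n_alba = 15L, n_orange = 15L, allele_freq_A = 0.2,
        depth_mean = 25, missing_rate = 0.05
      ),
      association = list(method = "fisher", fdr_level = 0.05),
      insertion = list(
        baseline_depth = 30, insertion_length = 3000L,
        t_low = 0.2, t_high = 0.75, min_flanking_depth = 5
      ),
      morph = list(
        granule_means = c(alba = 66.9, orange = 126.9),
        granule_dispersion = 30, granule_n = 3L, squares = 3L,
        lipid_n_per_group = 16L, lipid_morph_effect = 6
      )
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding both default and file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_lists <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_lists(base[[nm]], new[[nm]])
      } else {
        new[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$morph$granule_means)) {
    cfg$morph$granule_means <- unlist(cfg$morph$granule_means)
  }
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full mapping pipeline
#'
#' simulate -> per-cross BSA filters -> contig intersection ->
#' case/control association -> insertion depth genotyping -> morph
#' statistics, from one configuration and one seed. Every stage writes
#' its inputs and outputs as plain files (sync, VCF, BED, TSV, JSON)
#' under `outdir` so stages can be re-run or inspected standalone, and
#' the returned mapping report is bit-reproducible from config + seed.
#'
#' @param config a `run_config` ([default_run_config()] or
#'   [read_run_config()]).
#' @param outdir output directory; overrides `config$outdir`.
#' @param seed run seed; overrides `config$seed`.
#' @param stages character subset of
#'   `c("bsa", "association", "insertion", "morph")` to execute after
#'   the (always-run, cheap) simulation; default all.
#' @return An object of class `mapping_report`.
#' @examples
#' \donttest{
#' rep <- run_all(default_run_config(seed = 42))
#' rep$bsa$associated_contigs
#' }
#' @export
run_all <- function(config = default_run_config(), outdir = NULL, seed = NULL,
                    stages = c("bsa", "association", "insertion", "morph")) {
  stopifnot(inherits(config, "run_config"))
  if (length(stages) > 0L) {
    stages <- match.arg(stages, several.ok = TRUE)
  }
  seed <- as.integer(seed %||% config$seed)
  outdir <- outdir %||% config$outdir %||%
    file.path(tempdir(), sprintf("albamap_run_seed%d", seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  genome <- .stage("config", do.call(genome_spec, config$genome))
  report <- list(
    seed = seed, outdir = outdir,
    truth = list(
      causal_contig = genome$causal_contig,
      causal_pos = genome$causal_pos
    )
  )

  # --- simulate crosses and pools -----------------------------------------
  designs <- names(config$crosses)
  crosses <- list()
  syncs <- list()
  for (i in seq_along(designs)) {
    d <- designs[i]
    crosses[[d]] <- .stage(paste0("simulate:", d), {
      cc <- do.call(cross_config, c(config$crosses[[d]],
        list(design = d, seed = derive_seed(seed, i))))
      simulate_cross(cc, genome)
    })
    syncs[[d]] <- .stage(paste0("sequence:", d), {
      s <- simulate_cross_pools(crosses[[d]])
      write_sync(s, file.path(outdir, paste0(d, ".sync")))
      s
    })
  }

  # --- BSA filters + contig intersection ----------------------------------
  if ("bsa" %in% stages) {
    verdicts <- list()
    for (d in designs) {
      verdicts[[d]] <- .stage(paste0("bsa:", d), {
        v <- bsa_verdicts(syncs[[d]], d,
          cross_thresholds(d, hom_tol = config$bsa$hom_tol))
        write_tsv(v, file.path(outdir, paste0(d, "_verdicts.tsv")))
        v
      })
    }
    contig_calls <- .stage("bsa:contigs", {
      cc <- call_contigs(verdicts, min_snps = config$bsa$min_snps,
        contigs = genome$contigs)
      write_tsv(cc, file.path(outdir, "contig_calls.tsv"))
      cc
    })
    associated <- contig_calls$contig[contig_calls$associated]
    report$bsa <- list(
      contig_calls = contig_calls,
      associated_contigs = associated,
      causal_recovered = genome$causal_contig %in% associated,
      causal_unique = identical(associated, genome$causal_contig)
    )
  }

  # --- association panel ---------------------------------------------------
  if ("association" %in% stages) {
    panel <- .stage("association:simulate", {
      p <- do.call(simulate_panel, c(list(genome = genome),
        config$panel, list(seed = derive_seed(seed, 10L))))
      write_panel_vcf(p, file.path(outdir, "panel.vcf"))
      write_tsv(p$samples, file.path(outdir, "panel_phenotypes.tsv"))
      p
    })
    assoc <- .stage("association:test", {
      a <- associate_panel(filter_panel_sites(panel),
        method = config$association$method,
        fdr_level = config$association$fdr_level)
      write_tsv(a, file.path(outdir, "association.tsv"))
      a
    })
    sig <- assoc[assoc$significant, , drop = FALSE]
    report$association <- list(
      n_sites_tested = nrow(assoc),
      n_significant = nrow(sig),
      significant_contigs = sort(unique(sig$contig)),
      causal_site_significant = any(
        sig$contig == genome$causal_contig & sig$pos == genome$causal_pos
      )
    )
    if ("bsa" %in% stages) {
      report$association$nested_in_bsa <-
        all(sig$contig %in% report$bsa$associated_contigs)
    }
  }

  # --- insertion genotyping ------------------------------------------------
  if ("insertion" %in% stages && "association" %in% stages) {
    ins <- .stage("insertion", {
      windows <- insertion_windows(
        contig = genome$causal_contig,
        insertion_start = genome$causal_pos + 1L,
        insertion_length = config$insertion$insertion_length
      )
      write_bed(windows, file.path(outdir, "windows.bed"))
      truth_gt <- panel$truth$causal_genotype
      depths <- simulate_depth_windows(truth_gt,
        baseline_depth = config$insertion$baseline_depth,
        window_defs = windows, seed = derive_seed(seed, 20L))
      write_tsv(depths, file.path(outdir, "depth_windows.tsv"))
      calls <- genotype_insertions(depths,
        t_low = config$insertion$t_low, t_high = config$insertion$t_high,
        min_flanking_depth = config$insertion$min_flanking_depth)
      write_tsv(calls, file.path(outdir, "insertion_calls.tsv"))
      list(calls = calls, truth = truth_gt)
    })
    ok <- !is.na(ins$calls$class)
    agree <- ins$calls$class[ok] ==
      ins$truth[match(ins$calls$individual[ok], names(ins$truth))]
    report$insertion <- list(
      n_classified = sum(ok),
      n_unclassifiable = sum(!ok),
      truth_agreement = mean(agree),
      all_match_morph = all(
        (ins$calls$class[ok] != "aa") ==
          grepl("^alba", ins$calls$individual[ok])
      )
    )
  }

  # --- morph statistics ----------------------------------------------------
  if ("morph" %in% stages) {
    morph <- .stage("morph", {
      gr <- simulate_morph_measurements(
        group_means = config$morph$granule_means,
        dispersion = config$morph$granule_dispersion,
        n_per_group = config$morph$granule_n,
        squares_per_individual = config$morph$squares,
        seed = derive_seed(seed, 30L)
      )
      write_tsv(gr, file.path(outdir, "granule_counts.tsv"))
      per_ind <- aggregate(count ~ group + individual, gr, aggregate_squares)
      wt_gr <- welch_t(
        per_ind$count[per_ind$group == "alba"],
        per_ind$count[per_ind$group == "orange"]
      )

      li <- simulate_lipid_table(
        n_per_group = config$morph$lipid_n_per_group,
        morph_effect = config$morph$lipid_morph_effect,
        seed = derive_seed(seed, 31L)
      )
      write_tsv(li[, setdiff(names(li), "true_total_nmol")],
        file.path(outdir, "lipid_table.tsv"))
      corrected <- mass_correct(total_lipid(li), li$abdomen_mass_mg)
      wt_li <- welch_t(corrected[li$morph == "alba"],
        corrected[li$morph == "orange"])

      stats_df <- data.frame(
        comparison = c("granules_alba_vs_orange", "lipid_alba_vs_orange"),
        t = c(wt_gr$t, wt_li$t), df = c(wt_gr$df, wt_li$df),
        p = c(wt_gr$p, wt_li$p),
        ci_low = c(wt_gr$ci[1], wt_li$ci[1]),
        ci_high = c(wt_gr$ci[2], wt_li$ci[2]),
        mean_alba = c(wt_gr$mean_x, wt_li$mean_x),
        mean_orange = c(wt_gr$mean_y, wt_li$mean_y)
      )
      write_tsv(stats_df, file.path(outdir, "morph_stats.tsv"))
      list(granules = wt_gr, lipids = wt_li)
    })
    report$morph <- morph
  }

  .stage("report", {
    truth <- list(
      causal_contig = genome$causal_contig,
      causal_pos = genome$causal_pos,
      seed = seed
    )
    if ("association" %in% stages) {
      truth$panel_causal_genotypes <- as.list(panel$truth$causal_genotype)
    }
    write_truth(truth, file.path(outdir, "truth.json"))
  })
  class(report) <- "mapping_report"
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report> seed %d (%s)\n", x$seed, x$outdir))
  cat(sprintf("  true causal locus: %s:%d\n", x$truth$causal_contig, x$truth$causal_pos))
  if (!is.null(x$bsa)) {
    cat(sprintf(
      "  BSA: %d associated contig(s) [%s]; causal recovered: %s (unique: %s)\n",
      length(x$bsa$associated_contigs),
      paste(x$bsa$associated_contigs, collapse = ", "),
      x$bsa$causal_recovered, x$bsa$causal_unique
    ))
  }
  if (!is.null(x$association)) {
    cat(sprintf(
      "  association: %d/%d sites significant (FDR); causal site significant: %s\n",
      x$association$n_significant, x$association$n_sites_tested,
      x$association$causal_site_significant
    ))
    if (!is.null(x$association$nested_in_bsa)) {
      cat(sprintf("  significant sites nested in BSA contigs: %s\n",
        x$association$nested_in_bsa))
    }
  }
  if (!is.null(x$insertion)) {
    cat(sprintf(
      "  insertion genotyping: %d classified, agreement with truth %.1f%%\n",
      x$insertion$n_classified, 100 * x$insertion$truth_agreement
    ))
  }
  if (!is.null(x$morph)) {
    cat(sprintf(
      "  morph stats: granules t = %.2f (p = %.3g); lipids t = %.2f (p = %.3g)\n",
      x$morph$granules$t, x$morph$granules$p,
      x$morph$lipids$t, x$morph$lipids$p
    ))
  }
  invisible(x)
}
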