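#' Run configuration for a robustness analysis
#'
#' Describes a full robustness run: the cohort (subjects with one or two
#' replicate images + masks, given either as NIfTI file paths or as
#' in-memory objects/phantom specs), the perturbation chains to evaluate,
#' the processing configuration, manifest restrictions, the base seed and
#' the output directory.
#'
#' @param subjects List of subjects. Each subject is a list with `id` and
#'   `replicates`: a list of one or two replicate entries, each either
#'   `list(image = <path or vol_image>, mask = <path or roi_mask>)` or
#'   `list(phantom = <phantom_spec>)`.
#' @param chains Character vector of chain labels from the registry, or a
#'   list of [perturbation_chain()] objects.
#' @param processing A [processing_config()].
#' @param registry Chain registry (defaults to [default_chain_registry()]).
#' @param base_seed Integer base seed for all randomisation.
#' @param alpha Significance level of the ICC confidence interval.
#' @param threshold Robustness threshold on the CI.
#' @param output_dir Output directory for CSV results; `NULL` disables
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(subjects, chains = "N",
                       processing = processing_config(),
                       registry = default_chain_registry(),
                       base_seed = 1L, alpha = 0.05, threshold = 0.90,
                       output_dir = NULL) {
  if (is.character(chains)) {
    missing <- setdiff(chains, names(registry))
    if (length(missing)) {
      stop("unknown chain labels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    chains <- registry[chains]
  }
  structure(list(subjects = subjects, chains = chains,
                 processing = processing, base_seed = as.integer(base_seed),
                 alpha = alpha, threshold = threshold,
                 output_dir = output_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Pure report: checks chain labels against the registry, flags parameters
#' outside the conventional perturbation ranges (theta outside
#' \[-13, 13\] degrees, eta outside \[0, 0.75\], tau outside
#' \[-0.28, 0.28\] produce warnings, not errors) and missing input files.
#'
#' @param config A [run_config()], or a list with `chains` / `subjects`.
#' @param registry Chain registry used to resolve labels.
#' @return Data frame of findings with columns `severity`, `item`,
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(config, registry = default_chain_registry()) {
  findings <- list()
  note <- function(severity, item, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      severity = severity, item = item, message = message,
      stringsAsFactors = FALSE)
  }
  chains <- config$chains
  if (is.character(chains)) {
    for (lab in setdiff(chains, names(registry))) {
      note("error", lab, "unknown chain label")
    }
    chains <- registry[intersect(chains, names(registry))]
  }
  for (ch in chains) {
    if (length(ch$angles) && any(abs(ch$angles) > 13)) {
      note("warning", ch$label,
           "rotation angle outside default range [-13, 13] degrees")
    }
    if (length(ch$translations) &&
        any(ch$translations < 0 | ch$translations > 0.75)) {
      note("warning", ch$label,
           "translation fraction outside default range [0.00, 0.75]")
    }
    if (length(ch$taus) && any(abs(ch$taus) > 0.28)) {
      note("warning", ch$label,
           "volume fraction outside default range [-0.28, 0.28]")
    }
  }
  for (s in config$subjects) {
    for (rep in s$replicates) {
      for (f in c("image", "mask")) {
        if (is.character(rep[[f]]) && !file.exists(rep[[f]])) {
          note("error", s$id, paste0("missing file: ", rep[[f]]))
        }
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(severity = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

load_replicate <- function(rep) {
  if (!is.null(rep$phantom)) {
    ph <- generate_phantom(rep$phantom)
    return(list(image = ph$image, mask = ph$mask))
  }
  img <- if (is.character(rep$image)) read_image(rep$image) else rep$image
  msk <- if (is.character(rep$mask)) read_mask(rep$mask) else rep$mask
  list(image = img, mask = msk)
}

#' Run the full robustness analysis
#'
#' For every subject, replicate image and chain, expands the perturbation
#' chain per configured spacing, processes each perturbed sample
#' (interpolation, re-segmentation) and computes the manifest features;
#' then estimates per-feature perturbation ICCs (averaged over replicates
#' when two are present), classifies robustness against the threshold, and
#' — with two replicates — computes the test-retest ICC from unperturbed
#' features and the comparison categories. Fully deterministic under
#' `base_seed`.
#'
#' @param config A [run_config()].
#' @param manifest Optional manifest (defaults to the full manifest of the
#'   processing config).
#' @return List with `features` (per-sample feature data frame), `icc`
#'   (named list per chain of per-feature ICC data frames), `summary`
#'   (robust/non-robust/indeterminate fractions per chain), `comparison`
#'   (per-feature comparison categories per chain; `NULL` with one
#'   replicate) and `log` (run metadata). CSV files are written to
#'   `config$output_dir` when set.
#' @export
run_robustness <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  proc <- config$processing
  if (is.null(manifest)) manifest <- build_manifest(proc)
  spacings <- unique(manifest$spacing)
  n_rep <- length(config$subjects[[1]]$replicates)

  feature_rows <- list()
  unperturbed <- list()
  sample_counts <- list()

  for (subj in config$subjects) {
    for (rix in seq_along(subj$replicates)) {
      rep_data <- load_replicate(subj$replicates[[rix]])
      # unperturbed features (test-retest reference)
      base_vals <- extract_features(rep_data$image, rep_data$mask, proc,
                                    manifest)
      unperturbed[[paste(subj$id, rix)]] <-
        c(list(subject = subj$id, replicate = rix), as.list(base_vals))
      for (ch in config$chains) {
        seed_sr <- derive_seed(config$base_seed, subj$id, rix)
        noise_sd <- if (ch$noise_reps > 0) {
          estimate_noise_sd(rep_data$image)
        } else {
          NULL
        }
        vals_by_sample <- NULL
        for (sp in spacings) {
          man_sp <- manifest[manifest$spacing == sp, ]
          samples <- expand_chain(ch, rep_data$image, rep_data$mask, proc,
                                  spacing = sp, base_seed = seed_sr,
                                  noise_sd = noise_sd)
          sample_counts[[ch$label]] <- length(samples)
          for (si in seq_along(samples)) {
            s <- samples[[si]]
            morph <- s$mask
            vals <- tryCatch({
              int <- resegment(s$image, morph, proc)
              compute_features(s$image, morph, int, man_sp, proc)
            }, error = function(e) {
              stats::setNames(rep(NA_real_, nrow(man_sp)), man_sp$id)
            })
            if (is.null(vals_by_sample)) {
              vals_by_sample <- matrix(
                NA_real_, nrow = length(samples), ncol = nrow(manifest),
                dimnames = list(NULL, manifest$id))
            }
            vals_by_sample[si, names(vals)] <- vals
          }
        }
        for (si in seq_len(nrow(vals_by_sample))) {
          feature_rows[[length(feature_rows) + 1]] <-
            c(list(subject = subj$id, replicate = rix, chain = ch$label,
                   sample = si), as.list(vals_by_sample[si, ]))
        }
      }
    }
  }

  features <- do.call(rbind, lapply(feature_rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  unpert_df <- do.call(rbind, lapply(unperturbed, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))

  # per-chain, per-feature perturbation ICC
  icc_tables <- list()
  summaries <- list()
  comparisons <- list()

  # test-retest reference (two replicates)
  tr_labels <- NULL
  if (n_rep >= 2) {
    tr_labels <- vapply(manifest$id, function(fid) {
      panel <- build_panel(unpert_df, fid, by_replicate = TRUE)
      if (is.null(panel)) return("indeterminate")
      icc_record(panel, config$alpha, config$threshold, fid)$label
    }, character(1))
  }

  for (ch in config$chains) {
    sub <- features[features$chain == ch$label, ]
    recs <- lapply(manifest$id, function(fid) {
      panels <- lapply(seq_len(n_rep), function(rix) {
        build_panel(sub[sub$replicate == rix, ], fid)
      })
      if (any(vapply(panels, is.null, logical(1)))) {
        return(list(feature = fid, estimate = NA_real_, lower = NA_real_,
                    upper = NA_real_, n = NA_integer_, k = NA_integer_,
                    undefined = TRUE, label = "indeterminate"))
      }
      if (n_rep >= 2) {
        perturbation_icc(panels[[1]], panels[[2]], config$alpha,
                         config$threshold, fid)
      } else {
        icc_record(panels[[1]], config$alpha, config$threshold, fid)
      }
    })
    tab <- data.frame(
      feature = manifest$id,
      estimate = vapply(recs, function(r) r$estimate, numeric(1)),
      lower = vapply(recs, function(r) r$lower, numeric(1)),
      upper = vapply(recs, function(r) r$upper, numeric(1)),
      n = vapply(recs, function(r) as.numeric(r$n), numeric(1)),
      k = vapply(recs, function(r) as.numeric(r$k), numeric(1)),
      label = vapply(recs, function(r) r$label, character(1)),
      stringsAsFactors = FALSE)
    icc_tables[[ch$label]] <- tab
    counts <- table(factor(tab$label,
                           levels = c("robust", "non_robust",
                                      "indeterminate")))
    summaries[[ch$label]] <- data.frame(
      chain = ch$label,
      n_features = nrow(tab),
      robust = as.integer(counts["robust"]),
      non_robust = as.integer(counts["non_robust"]),
      indeterminate = as.integer(counts["indeterminate"]),
      frac_robust = as.numeric(counts["robust"]) / nrow(tab),
      frac_non_robust = as.numeric(counts["non_robust"]) / nrow(tab),
      frac_indeterminate = as.numeric(counts["indeterminate"]) / nrow(tab),
      stringsAsFactors = FALSE)
    if (!is.null(tr_labels)) {
      cmp <- lapply(seq_len(nrow(tab)), function(i) {
        compare_conditions(tr_labels[[tab$feature[i]]], tab$label[i])
      })
      comparisons[[ch$label]] <- data.frame(
        chain = ch$label,
        feature = tab$feature,
        test_retest = tr_labels[tab$feature],
        perturbation = tab$label,
        category = vapply(cmp, function(x) x$category, character(1)),
        substate = vapply(cmp, function(x) x$substate, character(1)),
        stringsAsFactors = FALSE)
    }
  }

  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL
  comparison_df <- if (length(comparisons)) {
    cd <- do.call(rbind, comparisons)
    rownames(cd) <- NULL
    cd
  } else {
    NULL
  }

  log <- list(
    base_seed = config$base_seed,
    config_hash = derive_seed(config$base_seed,
                              paste(vapply(config$chains, `[[`, "",
                                           "label"), collapse = ","),
                              nrow(manifest)),
    n_subjects = length(config$subjects),
    n_replicates = n_rep,
    chain_sizes = sample_counts,
    n_features = nrow(manifest),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(features = features, unperturbed = unpert_df,
                 icc = icc_tables, summary = summary_df,
                 comparison = comparison_df, log = log)
  if (!is.null(config$output_dir)) {
    write_outputs(result, config$output_dir)
  }
  result
}

# subjects x measurements panel for one feature id; NULL when any cell is
# missing after listwise deletion leaves < 2 subjects
build_panel <- function(df, fid, by_replicate = FALSE) {
  if (!fid %in% names(df)) return(NULL)
  key <- if (by_replicate) df$replicate else df$sample
  panel <- tapply(df[[fid]], list(df$subject, key), identity)
  panel <- matrix(unlist(panel), nrow = nrow(panel),
                  dimnames = dimnames(panel))
  keep <- rowSums(!is.finite(panel)) == 0
  panel <- panel[keep, , drop = FALSE]
  if (nrow(panel) < 2 || ncol(panel) < 2) return(NULL)
  panel
}

write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$features, file.path(dir, "features.csv"),
            row.names = FALSE)
  write.csv(result$unperturbed, file.path(dir, "features_unperturbed.csv"),
            row.names = FALSE)
  for (lab in names(result$icc)) {
    write.csv(result$icc[[lab]], file.path(dir, paste0("icc_", lab, ".csv")),
              row.names = FALSE)
  }
  write.csv(result$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(result$comparison)) {
    write.csv(result$comparison, file.path(dir, "comparison.csv"),
              row.names = FALSE)
  }
  log_lines <- c(
    sprintf("base_seed: %d", result$log$base_seed),
    sprintf("config_hash: %d", result$log$config_hash),
    sprintf("n_subjects: %d", result$log$n_subjects),
    sprintf("n_replicates: %d", result$log$n_replicates),
    sprintf("n_features: %d", result$log$n_features),
    vapply(names(result$log$chain_sizes), function(lab) {
      sprintf("chain_%s_samples: %d", lab, result$log$chain_sizes[[lab]])
    }, character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
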