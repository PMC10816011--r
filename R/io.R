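# CSV readers/writers with schema validation and the umbrella pipeline.

# column -> required type per schema; validators return a row-level error
# message or NA
TABLE_SCHEMAS <- list(
  colonies = list(
    required = c("oxygen", "quality", "plating", "dose_Gy", "seeded",
                 "colonies", "replicate"),
    numeric = c("dose_Gy", "seeded", "colonies"),
    check_row = function(r) {
      if (!is.finite(r$dose_Gy) || r$dose_Gy < 0) return("dose_Gy must be >= 0")
      if (!is.finite(r$seeded) || r$seeded < 1) return("seeded must be >= 1")
      if (!is.finite(r$colonies) || r$colonies < 0) {
        return("colonies must be >= 0")
      }
      if (r$colonies > r$seeded) return("colonies exceed seeded cells")
      NA_character_
    }
  ),
  histogram = list(
    required = c("bin_center", "count"),
    numeric = c("bin_center", "count"),
    check_row = function(r) {
      if (!is.finite(r$bin_center)) return("bin_center not numeric")
      if (!is.finite(r$count) || r$count < 0) return("count must be >= 0")
      NA_character_
    }
  ),
  foci = list(
    required = c("condition", "dose_Gy", "timepoint_h", "nucleus_id",
                 "foci_count"),
    numeric = c("dose_Gy", "timepoint_h", "foci_count"),
    check_row = function(r) {
      if (!is.finite(r$dose_Gy) || r$dose_Gy < 0) return("dose_Gy must be >= 0")
      if (!is.finite(r$timepoint_h) || r$timepoint_h < 0) {
        return("timepoint_h must be >= 0")
      }
      if (!is.finite(r$foci_count) || r$foci_count < 0 ||
          r$foci_count != round(r$foci_count)) {
        return("foci_count must be a non-negative integer")
      }
      NA_character_
    }
  )
)

#' Read and validate a CSV table
#'
#' Reads a comma-separated file (header row, dot decimal, UTF-8) and
#' validates it against one of the package schemas. A missing required
#' column is a hard error; rows failing validation are dropped with a
#' warning that carries their line numbers and are returned in the
#' `rejected` attribute.
#'
#' @param path file path.
#' @param schema one of `"colonies"`, `"histogram"`, `"foci"`.
#' @return The validated data frame, with attribute `rejected` (a data
#'   frame of dropped rows with `line` and `reason`).
#' @export
read_table <- function(path, schema = c("colonies", "histogram", "foci")) {
  schema <- match.arg(schema)
  sc <- TABLE_SCHEMAS[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty table: ", path, call. = FALSE)
  }
  # foci tables may carry oxygen/quality instead of a combined condition
  if (schema == "foci" && !"condition" %in% names(df) &&
      all(c("oxygen", "quality") %in% names(df))) {
    df$condition <- paste(df$quality, df$oxygen, sep = "/")
  }
  missing <- setdiff(sc$required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in sc$numeric) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (nrow(df)) {
    reasons <- vapply(seq_len(nrow(df)),
                      function(i) sc$check_row(df[i, , drop = FALSE]),
                      character(1))
  } else {
    reasons <- character(0)
  }
  bad <- !is.na(reasons)
  rejected <- df[bad, , drop = FALSE]
  if (any(bad)) {
    rejected$line <- which(bad) + 1L  # header is line 1
    rejected$reason <- reasons[bad]
    warning(sum(bad), " row(s) rejected in ", path, " (lines ",
            paste(rejected$line, collapse = ", "), ")", call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a data frame as CSV
#'
#' Comma-separated, header row, dot decimal, no row names, full precision.
#'
#' @param df data frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the configuration for [run_pipeline()].
#'
#' @param path optional YAML file; its fields override the defaults below.
#' @param seed global seed driving all generator substreams.
#' @param out_dir output directory.
#' @param let_keV_um beam LET, keV/µm.
#' @param mean_area_um2,sd_area_um2 nucleus geometry, µm².
#' @param doses_Gy dose list for the traversal table.
#' @param simulate generate synthetic inputs (the only mode when no input
#'   files are given).
#' @param counts_csv,foci_csv optional measured input tables; when `NULL`
#'   and `simulate` is `TRUE`, synthetic data are generated.
#' @param stages character vector of stages to run.
#' @return List of class `run_config`.
#' @export
run_config <- function(path = NULL, seed = 1L, out_dir = "results",
                       let_keV_um = 73, mean_area_um2 = 118.8,
                       sd_area_um2 = 52.5,
                       doses_Gy = c(0.5, 1, 2, 4, 8),
                       simulate = TRUE,
                       counts_csv = NULL, foci_csv = NULL,
                       stages = c("survival", "traversals", "cellcycle",
                                  "foci")) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              let_keV_um = let_keV_um, mean_area_um2 = mean_area_um2,
              sd_area_um2 = sd_area_um2, doses_Gy = doses_Gy,
              simulate = simulate, counts_csv = counts_csv,
              foci_csv = foci_csv, stages = stages)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    override <- yaml::read_yaml(path)
    cfg[names(override)] <- override
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: synthetic-data generation, survival fitting with
#' RBE/OER, the ion-traversal table, cell-cycle deconvolution over a
#' timecourse, and focus kinetics with the expected-vs-observed hit
#' comparison. Writes stage CSVs plus a machine-readable `results.json`
#' (carrying the seed and the full configuration for provenance) under
#' `config$out_dir`. Two runs with identical config and seed produce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the results list written to JSON.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  beam <- beam_spec(config$let_keV_um)
  geom <- nucleus_geometry(config$mean_area_um2, config$sd_area_um2)
  truth <- simulation_truth(let_keV_um = config$let_keV_um,
                            mean_area_um2 = config$mean_area_um2,
                            sd_area_um2 = config$sd_area_um2)
  results <- list(config = unclass(config), seed = config$seed)

  if ("survival" %in% config$stages) {
    counts <- run_stage("survival", {
      if (!is.null(config$counts_csv)) {
        read_table(config$counts_csv, "colonies")
      } else if (config$simulate) {
        simulate_colonies(truth, seed = config$seed)
      } else {
        stop("no colony counts configured")
      }
    })
    surv <- run_stage("survival", analyze_survival(counts))
    fits <- do.call(rbind, lapply(surv, function(s) {
      data.frame(condition = s$condition, pe = s$pe$pe, se_pe = s$pe$se,
                 d0_Gy = s$fit$d0_Gy, se_d0 = s$fit$se_d0,
                 n = s$fit$n, se_n = s$fit$se_n)
    }))
    rownames(fits) <- NULL
    write_table(counts, file.path(out, "colony_counts.csv"))
    write_table(fits, file.path(out, "shmt_fits.csv"))
    metrics <- run_stage("rbe_oer", {
      get_fit <- function(q, o, p) {
        hit <- vapply(surv, function(s) {
          identical(s$condition, paste(q, o, p, sep = "/"))
        }, logical(1))
        if (!any(hit)) NULL else surv[[which(hit)]]$fit
      }
      rows <- list()
      for (p in unique(truth$conditions$plating)) {
        for (o in unique(truth$conditions$oxygen)) {
          fx <- get_fit("xray", o, p); fc <- get_fit("carbon", o, p)
          if (!is.null(fx) && !is.null(fc)) {
            m <- rbe(fx, fc)
            rows[[length(rows) + 1L]] <- data.frame(
              metric = "rbe", comparison = paste0("carbon vs xray, ", o,
                                                  ", ", p),
              estimate = m$estimate, se = m$se)
          }
        }
        for (q in unique(truth$conditions$quality)) {
          fn <- get_fit(q, "normoxia", p); fh <- get_fit(q, "hypoxia", p)
          if (!is.null(fn) && !is.null(fh)) {
            m <- oer(fh, fn)
            rows[[length(rows) + 1L]] <- data.frame(
              metric = "oer", comparison = paste0("hypoxia vs normoxia, ",
                                                  q, ", ", p),
              estimate = m$estimate, se = m$se)
          }
        }
      }
      do.call(rbind, rows)
    })
    write_table(metrics, file.path(out, "rbe_oer.csv"))
    results$survival <- list(fits = fits, metrics = metrics)
  }

  if ("traversals" %in% config$stages) {
    tab <- run_stage("traversals",
                     traversal_table(config$doses_Gy, beam, geom))
    write_table(as.data.frame(tab), file.path(out, "traversals.csv"))
    results$traversals <- as.data.frame(tab)
  }

  if ("cellcycle" %in% config$stages) {
    cc <- run_stage("cellcycle", {
      fits <- lapply(seq_along(truth$cc_timepoints_h), function(i) {
        h <- simulate_dna_histogram(
          truth, seed = config$seed + i, condition = "normoxia",
          timepoint_h = truth$cc_timepoints_h[i], replicate = "r1")
        fit_djf(h)
      })
      summarize_timecourse(fits)
    })
    write_table(cc$timecourse, file.path(out, "cellcycle_timecourse.csv"))
    write_table(cc$grand, file.path(out, "cellcycle_grand.csv"))
    results$cellcycle <- cc
  } else {
    results$cellcycle <- "skipped"
  }

  if ("foci" %in% config$stages) {
    fk <- run_stage("foci", {
      dat <- if (!is.null(config$foci_csv)) {
        read_table(config$foci_csv, "foci")
      } else {
        simulate_foci(truth, seed = config$seed)
      }
      kin <- summarize_foci(dat)
      irr <- kin[kin$dose_Gy > 0, , drop = FALSE]
      decay <- fit_decay(irr)
      cmp <- expected_vs_observed(
        irr, mean_traversals(irr$dose_Gy[1], beam, geom))
      list(kinetics = kin, decay = unclass(decay), comparison = cmp)
    })
    write_table(as.data.frame(fk$kinetics), file.path(out, "foci_kinetics.csv"))
    write_table(fk$comparison, file.path(out, "foci_expected_vs_observed.csv"))
    results$foci <- fk
  }

  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(results)
}
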