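#' Pipeline run configuration
#'
#' Collects every tunable of the analysis chain with its default: the
#' neighborhood radius (45 km), the availability contour level (85%), the
#' focal home-range contour level (95%, with 75% and 50% as sensitivity
#' settings), the temporal window around death (3 seasons), the relocation
#' thresholds (5 for focal eligibility, 8 for the size regression), the
#' outlier rule, spline degrees of freedom, the selection criterion, and the
#' seed.
#'
#' @param out_dir output directory for pipeline stages.
#' @param focal_contour_level one of 95, 75, 50.
#' @param availability_level availability contour percent (default 85).
#' @param neighborhood_radius_m circle radius in meters (default 45000).
#' @param temporal_window_years seasons before/after death (default 3).
#' @param min_reloc_focal focal eligibility threshold (default 5).
#' @param min_reloc_hr size-regression threshold (default 8).
#' @param outlier_rule,outlier_k see [exclude_outliers()].
#' @param spline_df spline degrees of freedom for the size model.
#' @param criterion `"AICc"` or `"AIC"`.
#' @param sim a [sim_config()] used by the `simulate` stage.
#' @param seed integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = ".",
                       focal_contour_level = 95,
                       availability_level = 85,
                       neighborhood_radius_m = 45000,
                       temporal_window_years = 3,
                       min_reloc_focal = 5,
                       min_reloc_hr = 8,
                       outlier_rule = "distance",
                       outlier_k = 4,
                       spline_df = 3,
                       criterion = c("AICc", "AIC"),
                       sim = sim_config(),
                       seed = 1L) {
  stopifnot(focal_contour_level %in% c(95, 75, 50),
            availability_level > 0, availability_level < 100,
            neighborhood_radius_m > 0, temporal_window_years >= 0)
  structure(list(out_dir = out_dir,
                 focal_contour_level = focal_contour_level,
                 availability_level = availability_level,
                 neighborhood_radius_m = neighborhood_radius_m,
                 temporal_window_years = temporal_window_years,
                 min_reloc_focal = min_reloc_focal,
                 min_reloc_hr = min_reloc_hr,
                 outlier_rule = outlier_rule, outlier_k = outlier_k,
                 spline_df = spline_df,
                 criterion = match.arg(criterion),
                 sim = sim, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and validate a scat table
#'
#' Schema: `sample_id` (unique), `individual_id`, `sex` (`F`/`M`), `date`
#' (ISO-8601), `x`, `y` (finite, projected meters). Violations fail with the
#' offending file, row and column named.
#'
#' @param path CSV path.
#' @return Validated data frame with `date` parsed to `Date`.
#' @export
read_scats <- function(path) {
  # everything as character first: a column of "F" sex codes must not be
  # parsed as logical
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "individual_id", "sex", "date", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  dup <- which(duplicated(d$sample_id))
  if (length(dup))
    stop(path, ", row ", dup[1], ", column sample_id: duplicate ID ",
         d$sample_id[dup[1]])
  bad_sex <- which(!d$sex %in% c("F", "M"))
  if (length(bad_sex))
    stop(path, ", row ", bad_sex[1], ", column sex: unknown code '",
         d$sex[bad_sex[1]], "'")
  parsed <- as.Date(d$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) | d$date != format(parsed, "%Y-%m-%d"))
  if (length(bad))
    stop(path, ", row ", bad[1], ", column date: '", d$date[bad[1]],
         "' is not an ISO-8601 date")
  d$date <- parsed
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    nf <- which(!is.finite(v))
    if (length(nf))
      stop(path, ", row ", nf[1], ", column ", col, ": non-finite coordinate")
    d[[col]] <- v
  }
  d
}

#' Read and validate a mortality table
#'
#' Schema: `individual_id`, `death_date` (ISO-8601); optional `x`, `y`.
#'
#' @param path CSV path.
#' @return Validated data frame with `death_date` parsed to `Date`.
#' @export
read_mortality <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual_id", "death_date")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  parsed <- as.Date(d$death_date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) | d$death_date != format(parsed, "%Y-%m-%d"))
  if (length(bad))
    stop(path, ", row ", bad[1], ", column death_date: '",
         d$death_date[bad[1]], "' is not an ISO-8601 date")
  d$death_date <- parsed
  d
}

#' Write a contour polygon as GeoJSON
#'
#' Planar coordinates; the CRS is recorded as a free-text property rather
#' than a registered code because inputs are arbitrary projected meters.
#'
#' @param pvc a `pvc` object.
#' @param path output path.
#' @param crs free-text CRS tag.
#' @return `path`, invisibly.
#' @export
write_pvc_geojson <- function(pvc, path, crs = "projected-meters") {
  polys <- lapply(pvc$rings, function(r) {
    r <- rbind(r, r[1, , drop = FALSE])  # close ring
    list(unname(lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(crs = crs, level = pvc$level,
                               area_km2 = pvc$area_km2),
             features = lapply(polys, function(p)
               list(type = "Feature", properties = list(),
                    geometry = list(type = "Polygon", coordinates = p))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end territoriality analysis
#'
#' Runs the full chain on in-memory tables: focal selection, context
#' construction, RSF-table assembly, the saturated logistic mixed model, and
#' stratum selection coefficients.
#'
#' @param scats scat table (see [read_scats()] for the schema).
#' @param mortality mortality table.
#' @param config a [run_config()].
#' @return List with `focals`, `contexts`, `rsf`, `fit` (saturated model),
#'   `coefficients`.
#' @export
run_territory_analysis <- function(scats, mortality, config = run_config()) {
  focals <- select_focals(scats, mortality, config$min_reloc_focal)
  if (nrow(focals) == 0) stop("no focal individuals (>=",
                              config$min_reloc_focal,
                              " relocations and a death record)")
  contexts <- lapply(seq_len(nrow(focals)), function(i)
    build_context(focals[i, ], scats,
                  window = config$temporal_window_years,
                  radius = config$neighborhood_radius_m,
                  availability_level = config$availability_level,
                  focal_level = config$focal_contour_level,
                  outlier_rule = config$outlier_rule,
                  outlier_k = config$outlier_k))
  rsf <- assemble_rsf_table(contexts, seed = config$seed)
  saturated <- enumerate_candidate_models()
  saturated <- saturated[[length(saturated)]]
  fit <- fit_logistic_glmm(rsf, saturated)
  list(focals = focals, contexts = contexts, rsf = rsf, fit = fit,
       coefficients = selection_coefficients(fit))
}

#' Replicate-level recovery of the territoriality sign pattern
#'
#' Repeats the full chain - reference simulation ([study_simulation()]),
#' focal contexts, RSF table, saturated logistic mixed model, stratum
#' selection coefficients - over independent replicates and scores each
#' against the expected territorial pattern: both same-sex before-death
#' coefficients negative and significant (two-sided p < `alpha`), and all
#' after-death and opposite-sex coefficients non-significant.
#'
#' @param n_reps number of simulation replicates.
#' @param seed base seed; replicate r uses `seed + 10 * r`.
#' @param exclusion_prob same-sex exclusion probability while the owner
#'   lives (default 0.9).
#' @param alpha significance level for the pattern score (default 0.05).
#' @return List with `per_rep` (data frame `rep, seed, signal, null, pass`),
#'   `coefficients` (stacked per-replicate coefficient tables), and
#'   `recovery_rate` (fraction of replicates reproducing the full pattern).
#' @export
replicate_pattern_recovery <- function(n_reps = 50, seed = 1,
                                       exclusion_prob = 0.9, alpha = 0.05) {
  rows <- list(); cos <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 10L * r
    ss <- study_simulation(s, exclusion_prob = exclusion_prob)
    co <- tryCatch(
      suppressWarnings(suppressMessages(run_territory_analysis(
        ss$scats, ss$mortality, run_config(sim = ss$config, seed = s))))$coefficients,
      error = function(e) NULL)
    if (is.null(co)) {
      rows[[r]] <- data.frame(rep = r, seed = s, signal = NA, null = NA,
                              pass = FALSE)
      next
    }
    same <- co$sex_focal == co$sex_neighbor
    before <- co$period == "before"
    signal <- all(co$estimate[same & before] < 0 &
                  co$p[same & before] < alpha)
    null_ok <- all(co$p[!(same & before)] >= alpha)
    rows[[r]] <- data.frame(rep = r, seed = s, signal = signal,
                            null = null_ok, pass = signal && null_ok)
    co$rep <- r
    cos[[length(cos) + 1L]] <- co
  }
  per_rep <- do.call(rbind, rows)
  list(per_rep = per_rep,
       coefficients = do.call(rbind, cos),
       recovery_rate = mean(per_rep$pass))
}

stage_manifest <- function(config, stage, files, counts) {
  tmp <- tempfile()
  yaml::write_yaml(unclass(rapply(config, unclass, how = "replace")), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(stage = stage, config_md5 = h, seed = config$seed,
       files = files, row_counts = counts,
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

need_file <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path, "; run stage '", producer,
         "' first")
  path
}

#' Run one pipeline stage
#'
#' File-based workflow driver. Stages: `simulate` (writes the synthetic
#' dataset), `qc` (replicate consensus, quality index, individual matching,
#' probability-of-identity report), `homerange` (per-individual kernel and
#' MCP areas), `rsf` (focal contexts and the use-availability table), `fit`
#' (size regression and the saturated selection model), `report` (selection
#' coefficients at the configured focal level plus the 75% and 50%
#' sensitivity reruns). Every stage writes a JSON manifest (config hash,
#' seed, row counts) next to its artifacts and fails with the name of the
#' stage to run first when an upstream artifact is missing.
#'
#' @param stage one of `"simulate"`, `"qc"`, `"homerange"`, `"rsf"`,
#'   `"fit"`, `"report"`.
#' @param config a [run_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "qc", "homerange", "rsf",
                                "fit", "report"),
                      config = run_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir, c(scats = "scats.csv",
                                     mortality = "mortality.csv",
                                     replicates = "replicates.csv"))
  names(out) <- c("scats", "mortality", "replicates")
  files <- character(0); counts <- list()

  if (stage == "simulate") {
    terr <- simulate_population(config$sim)
    scats <- simulate_scats(terr, config$sim)
    reps <- simulate_genotype_replicates(scats, config$sim)
    write_simulation(config$out_dir, terr, scats, config$sim, replicates = reps)
    files <- out
    counts <- list(territories = nrow(terr), scats = nrow(scats),
                   replicates = nrow(reps))
  } else if (stage == "qc") {
    reps <- utils::read.csv(need_file(out["replicates"], "simulate"),
                            stringsAsFactors = FALSE)
    scats <- read_scats(need_file(out["scats"], "simulate"))
    sex <- stats::setNames(scats$sex, scats$sample_id)
    qc <- genotype_qc(reps, sex = sex)
    pid <- list(unrelated = pid_unrelated(config$sim$allele_freqs),
                sib = pid_sib(config$sim$allele_freqs))
    f1 <- file.path(config$out_dir, "consensus.csv")
    f2 <- file.path(config$out_dir, "individuals.csv")
    f3 <- file.path(config$out_dir, "pid_report.json")
    utils::write.csv(qc$consensus, f1, row.names = FALSE)
    utils::write.csv(qc$individuals, f2, row.names = FALSE)
    jsonlite::write_json(pid, f3, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2, f3)
    counts <- list(consensus = nrow(qc$consensus),
                   individuals = qc$individuals |> nrow())
  } else if (stage == "homerange") {
    scats <- read_scats(need_file(out["scats"], "simulate"))
    hr <- rbind(home_range_table(scats, level = 95,
                                 min_reloc = config$min_reloc_hr,
                                 estimator = "kernel"),
                home_range_table(scats, level = 95,
                                 min_reloc = config$min_reloc_hr,
                                 estimator = "mcp"))
    f1 <- file.path(config$out_dir, "homeranges.csv")
    utils::write.csv(hr, f1, row.names = FALSE)
    files <- f1
    counts <- list(homeranges = nrow(hr))
  } else if (stage == "rsf") {
    scats <- read_scats(need_file(out["scats"], "simulate"))
    mort <- read_mortality(need_file(out["mortality"], "simulate"))
    focals <- select_focals(scats, mort, config$min_reloc_focal)
    contexts <- lapply(seq_len(nrow(focals)), function(i)
      build_context(focals[i, ], scats,
                    window = config$temporal_window_years,
                    radius = config$neighborhood_radius_m,
                    availability_level = config$availability_level,
                    focal_level = config$focal_contour_level,
                    outlier_rule = config$outlier_rule,
                    outlier_k = config$outlier_k))
    for (ctx in contexts) {
      if (!isTRUE(ctx$usable)) {
        message("context ", ctx$focal_id, " unusable: ", ctx$reason)
        next
      }
      write_pvc_geojson(ctx$home_range,
                        file.path(config$out_dir,
                                  paste0("context_", ctx$focal_id, "_hr.geojson")))
      write_pvc_geojson(ctx$availability,
                        file.path(config$out_dir,
                                  paste0("context_", ctx$focal_id,
                                         "_availability.geojson")))
    }
    rsf <- assemble_rsf_table(contexts, seed = config$seed)
    f1 <- file.path(config$out_dir, "rsf_points.csv")
    utils::write.csv(as.data.frame(rsf), f1, row.names = FALSE)
    files <- f1
    counts <- list(rsf_points = nrow(rsf))
  } else if (stage == "fit") {
    hr <- utils::read.csv(need_file(file.path(config$out_dir, "homeranges.csv"),
                                    "homerange"), stringsAsFactors = FALSE)
    rsf <- utils::read.csv(need_file(file.path(config$out_dir, "rsf_points.csv"),
                                     "rsf"), stringsAsFactors = FALSE)
    hr_fit <- fit_hr_size_model(hr[hr$estimator == "kernel", ],
                                spline_df = config$spline_df)
    f1 <- file.path(config$out_dir, "hr_model.json")
    jsonlite::write_json(list(sex_coefficient = hr_fit$sex_coefficient,
                              ratio = hr_fit$ratio,
                              predictions = hr_fit$predictions),
                         f1, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    saturated <- enumerate_candidate_models()
    fit <- fit_logistic_glmm(rsf, saturated[[length(saturated)]])
    f2 <- file.path(config$out_dir, "selection_coefficients.csv")
    utils::write.csv(selection_coefficients(fit), f2, row.names = FALSE)
    files <- c(f1, f2)
    counts <- list(rsf_points = nrow(rsf))
  } else if (stage == "report") {
    scats <- read_scats(need_file(out["scats"], "simulate"))
    mort <- read_mortality(need_file(out["mortality"], "simulate"))
    res <- lapply(c(config$focal_contour_level, 75, 50), function(lev) {
      cfg <- config
      cfg$focal_contour_level <- lev
      co <- run_territory_analysis(scats, mort, cfg)$coefficients
      co$focal_level <- lev
      co
    })
    tab <- unique(do.call(rbind, res))
    f1 <- file.path(config$out_dir, "report_selection_coefficients.csv")
    utils::write.csv(tab, f1, row.names = FALSE)
    files <- f1
    counts <- list(coefficients = nrow(tab))
  }

  mf <- stage_manifest(config, stage, files, counts)
  jsonlite::write_json(mf, file.path(config$out_dir,
                                     paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(as.list(files))
}
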