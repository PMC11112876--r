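# End-to-end analysis runs: several conditions x replicas in, tidy metric
# tables, summaries, bridged-protomer counts and per-protomer significance
# flags out. Output is byte-reproducible: fixed row ordering, fixed float
# formatting (4 decimals in TSV, full precision in JSON metadata).

#' Configure an analysis run
#'
#' @param conditions named list; each element is one condition holding a
#'   list of replica inputs, each either a [trajectory] or a path to a
#'   multi-model PDB file.
#' @param channel a [channel_definition].
#' @param reference optional name of the reference condition (enables the
#'   per-protomer significance table for the other conditions).
#' @param analyses subset of `c("rmsd", "rmsf", "bridges", "tm_geometry",
#'   "pocket_water")`.
#' @param bridge_pairs list of residue-number pairs for the bridge
#'   analysis; defaults to 33-162, 158-223 and 158-162.
#' @param alpha significance level for the reference comparison.
#' @param frame_range optional `c(first, last)` 1-based frame window
#'   applied to every replica (default: all frames).
#' @param dt_ps frame spacing assigned to trajectories read from file.
#' @param out_dir output directory (created if needed).
#' @return list of class `run_config`.
#' @export
run_config <- function(conditions, channel, reference = NULL,
                       analyses = c("rmsd", "rmsf", "bridges",
                                    "tm_geometry", "pocket_water"),
                       bridge_pairs = list(c(33, 162), c(158, 223),
                                           c(158, 162)),
                       alpha = 0.05, frame_range = NULL, dt_ps = 1,
                       out_dir = tempfile("hexchannel_run_")) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list")
  }
  if (!is.null(reference) && !(reference %in% names(conditions))) {
    stop("reference condition '", reference, "' not among the conditions")
  }
  if (any(lengths(conditions) < 1L)) {
    stop("every condition needs at least one replica")
  }
  stopifnot(inherits(channel, "channel_definition"))
  structure(list(conditions = conditions, channel = channel,
                 reference = reference, analyses = analyses,
                 bridge_pairs = bridge_pairs, alpha = alpha,
                 frame_range = frame_range, dt_ps = dt_ps,
                 out_dir = out_dir),
            class = "run_config")
}

.load_replica <- function(x, dt_ps) {
  if (inherits(x, "trajectory")) x
  else if (is.character(x)) read_pdb_models(x, dt_ps = dt_ps)
  else stop("replica must be a trajectory or a PDB file path")
}

.fmt_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("frame", "replica", "n_bridged", "n_ref", "n_cmp", "n"))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.4f", df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# tidy rows helper
.rows <- function(metric, condition, replica, protomer, frame, time_ps,
                  value) {
  data.frame(metric = metric, condition = condition, replica = replica,
             protomer = protomer, frame = frame, time_ps = time_ps,
             value = value, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Computes every enabled metric for every condition and replica and
#' writes, under `config$out_dir`: `metrics.tsv` (tidy per-frame values;
#' for RMSF the `frame` column carries the residue number and `time_ps` is
#' NA), `summary.tsv` (per metric/condition/protomer box-plot summaries
#' over pooled frames and replicas), `bridged_counts.tsv` (protomers per
#' condition in which each residue pair is bridged, occupancy pooled over
#' replicas), `significance.tsv` (per-protomer Kruskal-Wallis flags vs the
#' reference condition, when one is configured), and `run_metadata.json`
#' (package version, conventions, frame range).
#'
#' @param config a [run_config].
#' @return invisibly, a list with the tables and output paths.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  chan <- config$channel
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  trajs <- lapply(config$conditions, function(reps) {
    lapply(reps, function(r) {
      tr <- .load_replica(r, config$dt_ps)
      if (!is.null(config$frame_range)) {
        tr <- subset_frames(tr, seq(config$frame_range[1],
                                    config$frame_range[2]))
      }
      tr
    })
  })

  metric_rows <- list()
  add <- function(df) metric_rows[[length(metric_rows) + 1L]] <<- df

  for (cond in names(trajs)) {
    for (r in seq_along(trajs[[cond]])) {
      tr <- trajs[[cond]][[r]]
      tt <- frame_times(tr)
      ca_all <- select_atoms(tr, chain = chan$protomer_chains,
                             atom_names = "CA")
      if ("rmsd" %in% config$analyses) {
        v <- rmsd_series(tr, ca_all, reference_frame = 1L)
        add(.rows("rmsd", cond, r, "all", seq_along(v), tt, v))
      }
      if ("rmsf" %in% config$analyses && n_frames(tr) >= 2L) {
        v <- rmsf_per_residue(tr, ca_all)
        lab <- strsplit(names(v), ":", fixed = TRUE)
        add(.rows("rmsf", cond, r,
                  vapply(lab, `[`, "", 1L),
                  as.integer(vapply(lab, `[`, "", 2L)), NA_real_,
                  unname(v)))
      }
      if ("bridges" %in% config$analyses) {
        for (pair in config$bridge_pairs) {
          mname <- sprintf("bridge_%d_%d", pair[1], pair[2])
          for (ch in chan$protomer_chains) {
            br <- saltbridge_series(tr, chan,
                                    list(chain = ch, resno = pair[1]),
                                    list(chain = ch, resno = pair[2]))
            add(.rows(mname, cond, r, ch, seq_along(br$series), tt,
                      br$series))
          }
        }
      }
      if ("tm_geometry" %in% config$analyses) {
        for (ch in chan$protomer_chains) {
          d13 <- tm_distance(tr, chan, ch, "TM1-TM3")
          d24 <- tm_distance(tr, chan, ch, "TM2-TM4")
          add(.rows("tm13_distance", cond, r, ch, seq_along(d13), tt, d13))
          add(.rows("tm24_distance", cond, r, ch, seq_along(d24), tt, d24))
          for (tm in c("TM2", "TM3", "TM4")) {
            v <- tm_inclination(tr, chan, ch, tm)
            add(.rows(paste0("incl_", tm), cond, r, ch, seq_along(v), tt, v))
          }
        }
      }
      if ("pocket_water" %in% config$analyses) {
        for (ch in chan$protomer_chains) {
          v <- pocket_water_count(tr, chan, ch, quiet = TRUE)
          add(.rows("pocket_water", cond, r, ch, seq_along(v), tt,
                    as.numeric(v)))
        }
      }
    }
  }
  metrics <- do.call(rbind, metric_rows)
  ord <- order(metrics$metric, metrics$condition, metrics$replica,
               metrics$protomer, metrics$frame)
  metrics <- metrics[ord, , drop = FALSE]
  rownames(metrics) <- NULL

  # pooled summaries
  key <- interaction(metrics$metric, metrics$condition, metrics$protomer,
                     drop = TRUE)
  summary_rows <- lapply(levels(key), function(k) {
    sub <- metrics[key == k, ]
    s <- summarize_metric(sub$value)
    data.frame(metric = sub$metric[1], condition = sub$condition[1],
               protomer = sub$protomer[1], n = s$n, mean = s$mean,
               sd = s$sd, median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n_outliers = length(s$outliers), stringsAsFactors = FALSE)
  })
  summaries <- do.call(rbind, summary_rows)
  summaries <- summaries[order(summaries$metric, summaries$condition,
                               summaries$protomer), , drop = FALSE]
  rownames(summaries) <- NULL

  # bridged-protomer counts, occupancy pooled over replicas
  bridged <- NULL
  if ("bridges" %in% config$analyses) {
    rows <- list()
    for (cond in names(trajs)) {
      for (pair in config$bridge_pairs) {
        mname <- sprintf("bridge_%d_%d", pair[1], pair[2])
        n_b <- 0L
        for (ch in chan$protomer_chains) {
          sub <- metrics[metrics$metric == mname &
                         metrics$condition == cond &
                         metrics$protomer == ch, ]
          occ <- mean(sub$value <= chan$bridge_cutoff)
          if (occ >= 0.5) n_b <- n_b + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, pair = sprintf("%d-%d", pair[1], pair[2]),
          n_bridged = n_b, stringsAsFactors = FALSE)
      }
    }
    bridged <- do.call(rbind, rows)
    bridged <- bridged[order(bridged$condition, bridged$pair), ,
                       drop = FALSE]
    rownames(bridged) <- NULL
  }

  # per-protomer significance vs reference
  signif_tab <- NULL
  if (!is.null(config$reference) && length(trajs) > 1L) {
    per_prot <- metrics[metrics$protomer %in% chan$protomer_chains, ]
    rows <- list()
    for (cond in setdiff(names(trajs), config$reference)) {
      for (m in unique(per_prot$metric)) {
        sub <- per_prot[per_prot$metric == m &
                        per_prot$condition %in% c(config$reference, cond), ]
        if (length(unique(sub$condition)) != 2L) next
        tab <- data.frame(condition = sub$condition,
                          protomer = sub$protomer, value = sub$value,
                          stringsAsFactors = FALSE)
        cmp <- compare_to_reference(tab, reference = config$reference,
                                    alpha = config$alpha)
        cmp <- cbind(metric = m, condition = cond, cmp,
                     stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- cmp
      }
    }
    if (length(rows)) {
      signif_tab <- do.call(rbind, rows)
      signif_tab <- signif_tab[order(signif_tab$metric,
                                     signif_tab$condition,
                                     signif_tab$protomer), , drop = FALSE]
      rownames(signif_tab) <- NULL
    }
  }

  paths <- list(metrics = file.path(config$out_dir, "metrics.tsv"),
                summary = file.path(config$out_dir, "summary.tsv"),
                metadata = file.path(config$out_dir, "run_metadata.json"))
  .fmt_tsv(metrics, paths$metrics)
  .fmt_tsv(summaries, paths$summary)
  if (!is.null(bridged)) {
    paths$bridged <- file.path(config$out_dir, "bridged_counts.tsv")
    .fmt_tsv(bridged, paths$bridged)
  }
  if (!is.null(signif_tab)) {
    paths$significance <- file.path(config$out_dir, "significance.tsv")
    .fmt_tsv(signif_tab, paths$significance)
  }
  meta <- list(
    package = "hexchannel",
    version = as.character(utils::packageVersion("hexchannel")),
    analyses = config$analyses,
    reference = config$reference,
    alpha = config$alpha,
    frame_range = config$frame_range,
    conventions = list(
      bridge_cutoff_A = chan$bridge_cutoff,
      water_cutoff_A = chan$water_cutoff,
      bridge_classification = "occupancy >= 0.5 of analysed frames",
      quantiles = "linear interpolation (type 7)",
      axis_fit = "total least squares, N-to-C orientation",
      rmsd_selection = "Calpha, uniform weights",
      rmsf_alignment = "two-pass to the mean structure",
      pocket_centroid = "recomputed per frame",
      replica_sd = "sample s.d. (n - 1)"
    )
  )
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(list(metrics = metrics, summary = summaries, bridged = bridged,
                 significance = signif_tab, paths = paths))
}
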