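# File round-tripping for the package's tabular and parameter schemas.
# All exports are plain text (CSV / JSON) and write-read stable.

.check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    .err(sprintf("file '%s' is missing required column(s): %s",
                 file, paste(missing, collapse = ", ")),
         "gapcanal_schema_error")
  }
}

#' Write and read circuit parameters as JSON
#'
#' The parameter file has named blocks `R`, `T`, `bcd_weight`,
#' `ext_weight`, `h`, `lambda`, `D`, each keyed by gene name (`T` rows are
#' target genes, columns regulators; `ext_weight` columns are `cad`, `tll`;
#' `D` columns are the cleavage cycles).
#'
#' @param params A [circuit_parameters()] object.
#' @param path File path.
#' @return `write_parameters` invisibly returns `path`; `read_parameters`
#'   returns a `circuit_parameters` object equal to the one written.
#' @export
write_parameters <- function(params, path) {
  g <- gap_genes()
  as_named <- function(v) as.list(stats::setNames(as.numeric(v), g))
  obj <- list(
    genes = g,
    R = as_named(params$R),
    T = stats::setNames(lapply(g, function(a) as_named(params$T[a, ])), g),
    bcd_weight = as_named(params$bcd_weight),
    ext_weight = stats::setNames(
      lapply(g, function(a) as.list(stats::setNames(
        as.numeric(params$ext_weight[a, ]), c("cad", "tll")))), g),
    h = as_named(params$h),
    lambda = as_named(params$lambda),
    D = stats::setNames(
      lapply(g, function(a) as.list(stats::setNames(
        as.numeric(params$D[a, ]), c("13", "14A")))), g))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- gap_genes()
  for (block in c("R", "T", "bcd_weight", "ext_weight", "h", "lambda",
                  "D")) {
    if (is.null(obj[[block]])) {
      .err(sprintf("parameter file '%s' is missing block '%s'",
                   path, block), "gapcanal_schema_error")
    }
  }
  vec <- function(block) vapply(g, function(a) {
    v <- obj[[block]][[a]]
    if (is.null(v)) .err(sprintf(
      "parameter file '%s': block '%s' lacks gene '%s'", path, block, a),
      "gapcanal_schema_error")
    as.numeric(v)
  }, numeric(1))
  Tm <- t(vapply(g, function(a) vapply(
    g, function(b) as.numeric(obj$T[[a]][[b]]), numeric(1)),
    numeric(4L)))
  ew <- t(vapply(g, function(a) vapply(
    c("cad", "tll"), function(e) as.numeric(obj$ext_weight[[a]][[e]]),
    numeric(1)), numeric(2L)))
  D <- t(vapply(g, function(a) vapply(
    c("13", "14A"), function(cy) as.numeric(obj$D[[a]][[cy]]),
    numeric(1)), numeric(2L)))
  circuit_parameters(R = vec("R"), T_matrix = Tm,
                     bcd_weight = vec("bcd_weight"), ext_weight = ew,
                     h = vec("h"), lambda = vec("lambda"), D = D)
}

#' Write and read a Bcd ensemble CSV
#'
#' Columns: `embryo_id`, `A`, `l`, `normalization_tag`.
#'
#' @param ensemble A [bcd_ensemble()].
#' @param path File path.
#' @return The ensemble (read) or `path` (write, invisibly).
#' @export
write_ensemble <- function(ensemble, path) {
  df <- data.frame(embryo_id = ensemble$embryo_id, A = ensemble$A,
                   l = ensemble$l,
                   normalization_tag = attr(ensemble, "normalization_tag"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("embryo_id", "A", "l", "normalization_tag"), path)
  bcd_ensemble(df$A, df$l, df$embryo_id,
               normalization_tag = df$normalization_tag[1L])
}

#' Write and read per-embryo profile samples
#'
#' Columns: `embryo_id`, `x_percent_EL`, `concentration`.
#'
#' @param profiles Named list of data.frames with columns `x`, `intensity`.
#' @param path File path.
#' @return List of profiles (read) or `path` (write, invisibly).
#' @export
write_profiles <- function(profiles, path) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- as.character(seq_along(profiles))
  df <- do.call(rbind, lapply(seq_along(profiles), function(j) {
    data.frame(embryo_id = ids[j], x_percent_EL = profiles[[j]]$x,
               concentration = profiles[[j]]$intensity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("embryo_id", "x_percent_EL", "concentration"), path)
  out <- lapply(split(df, df$embryo_id), function(d) {
    d <- d[order(d$x_percent_EL), ]
    data.frame(x = d$x_percent_EL, intensity = d$concentration)
  })
  out[order(names(out))]
}

#' Write and read an external-input table CSV
#'
#' Columns: `factor`, `time_class`, `x_percent_EL`, `concentration`.
#'
#' @param table An [external_input_table()].
#' @param path File path.
#' @return The table (read) or `path` (write, invisibly).
#' @export
write_external_input <- function(table, path) {
  df <- expand.grid(x_percent_EL = table$x, time_class = 1:8)
  df$factor <- table$factor
  df$concentration <- as.vector(table$values)
  utils::write.csv(df[, c("factor", "time_class", "x_percent_EL",
                          "concentration")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_external_input
#' @export
read_external_input <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("factor", "time_class", "x_percent_EL",
                       "concentration"), path)
  x <- sort(unique(df$x_percent_EL))
  vals <- matrix(NA_real_, length(x), 8L)
  for (k in 1:8) {
    d <- df[df$time_class == k, ]
    vals[, k] <- d$concentration[match(x, d$x_percent_EL)]
  }
  if (anyNA(vals)) .err(sprintf(
    "file '%s' does not cover the full (x, time_class) grid", path),
    "gapcanal_schema_error")
  external_input_table(df$factor[1L], x, vals)
}

#' Write a basin partition CSV
#'
#' Columns: `position`, `attractor_label`, `c1`, `c2`, `n_samples`,
#' `unresolved_fraction`. Multiple partitions (one per position) may be
#' concatenated.
#'
#' @param partitions Named-by-position list of [sample_basin_partition()]
#'   results (or a single partition with `position`).
#' @param path File path.
#' @param position Position for a single unnamed partition.
#' @return Data frame as written (read) or `path` (write, invisibly).
#' @export
write_partitions <- function(partitions, path, position = NA_real_) {
  if (inherits(partitions, "basin_partition")) {
    partitions <- stats::setNames(list(partitions), position)
  }
  df <- do.call(rbind, lapply(names(partitions), function(px) {
    p <- partitions[[px]]
    data.frame(position = as.numeric(px),
               attractor_label = p$intervals$label,
               c1 = p$intervals$c1, c2 = p$intervals$c2,
               n_samples = p$n_samples,
               unresolved_fraction = p$unresolved_fraction)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  df <- utils::read.csv(path,
                        colClasses = c(attractor_label = "character"))
  .check_columns(df, c("position", "attractor_label", "c1", "c2",
                       "n_samples", "unresolved_fraction"), path)
  df
}

#' Write a basin-boundary curve CSV
#'
#' Columns: `boundary_id`, `x`, `hb_value`.
#'
#' @param curve A [basin_boundary_profile()] result.
#' @param path File path.
#' @return Data frame (read) or `path` (write, invisibly).
#' @export
write_boundary_curve <- function(curve, path) {
  df <- data.frame(boundary_id = paste(attr(curve, "pair"),
                                       collapse = "|"),
                   x = curve$x, hb_value = curve$hb)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundary_curve
#' @export
read_boundary_curve <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("boundary_id", "x", "hb_value"), path)
  df
}

#' Write per-profile classification records
#'
#' Columns: `profile_id`, `mechanism`, `transition`, `family`,
#' `solution_class`, `flags` — the machine-readable analogue of a
#' mechanism/family distribution table.
#'
#' @param records Data frame with those columns.
#' @param path File path.
#' @return Data frame (read) or `path` (write, invisibly).
#' @export
write_classification <- function(records, path) {
  .check_columns(records, c("profile_id", "mechanism", "transition",
                            "family", "solution_class", "flags"),
                 "classification records")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    mechanism = "character", transition = "character",
    family = "character", solution_class = "character",
    flags = "character"))
  .check_columns(df, c("profile_id", "mechanism", "transition", "family",
                       "solution_class", "flags"), path)
  df
}

#' Write a positional-variance summary CSV
#'
#' Columns: `row_label`, `family`, `n`, `full_range`, `sd` (the
#' family-stratified variance table layout).
#'
#' @param summary_df Output of [family_stratified_summary()].
#' @param path File path.
#' @return Data frame (read) or `path` (write, invisibly).
#' @export
write_summary <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path)
  .check_columns(df, c("row_label", "family", "n", "full_range", "sd"),
                 path)
  df
}
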