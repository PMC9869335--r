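# Interchange: self-describing YAML/JSON system files, delimited observable
# export, and native trajectory persistence.

#' Write an assembled CG system to a YAML or JSON file
#'
#' The file is self-describing (beads with positions/radii/charges/groups,
#' bonds tagged by kind, pocket indices) and is the canonical interchange
#' format between the builder and the sampling/estimation layers.
#'
#' @param system a `cg_system`.
#' @param path output file; format inferred from the extension unless given.
#' @param format `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "yaml"
  stopifnot(inherits(system, "cg_system"))
  obj <- list(
    format = "cgalchemy/system", version = 1L,
    is_ternary = system$is_ternary,
    beads = list(x = system$pos[, 1], y = system$pos[, 2], z = system$pos[, 3],
                 radius = system$radius, charge = system$charge,
                 group = system$group, molecule = system$molecule),
    bonds = list(i = as.integer(system$bonds[, 1]),
                 j = as.integer(system$bonds[, 2]),
                 r0 = system$bonds[, 3], k = system$bonds[, 4],
                 kind = c("enm", "linker", "anchor")[system$bonds[, 5]]),
    pocket = system$pocket
  )
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(obj, precision = 15), path)
  }
  invisible(path)
}

#' Read a CG system written by [write_system]
#' @param path YAML or JSON system file.
#' @return A `cg_system`.
#' @export
read_system <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(obj) || !identical(obj$format, "cgalchemy/system"))
    stop("not a cgalchemy system file: ", path)
  b <- obj$beads
  kind <- match(obj$bonds$kind, c("enm", "linker", "anchor"))
  structure(list(
    pos = cbind(as.numeric(b$x), as.numeric(b$y), as.numeric(b$z)),
    radius = as.numeric(b$radius), charge = as.numeric(b$charge),
    group = as.character(b$group), molecule = as.character(b$molecule),
    bonds = cbind(i = as.numeric(obj$bonds$i), j = as.numeric(obj$bonds$j),
                  r0 = as.numeric(obj$bonds$r0), k = as.numeric(obj$bonds$k),
                  kind = kind),
    pocket = lapply(obj$pocket, as.integer),
    is_ternary = isTRUE(obj$is_ternary)),
    class = "cg_system")
}

#' Export per-state observables as delimited text
#'
#' One row per retained frame: stage, state index, lambda, trajectory id,
#' frame index within trajectory, and dU/dlambda.
#'
#' @param leg_samples a `leg_samples` object from [sample_leg].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_observables <- function(leg_samples, path) {
  stopifnot(inherits(leg_samples, "leg_samples"))
  rows <- list()
  for (stg in names(leg_samples$stages)) {
    s <- leg_samples$stages[[stg]]
    for (k in seq_along(s$lambdas)) {
      id <- s$traj_id[[k]]
      frame <- stats::ave(seq_along(id), id, FUN = seq_along)
      rows[[length(rows) + 1]] <- data.frame(
        stage = stg, state = k, lambda = s$lambdas[k], traj = id,
        frame = frame, dudl = s$dudl[[k]])
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a trajectory (native serialization)
#'
#' Binary persistence for runtime artifacts (positions, observables,
#' metadata); use [export_observables] for a plain-text view.
#' @param trajectory a `cg_trajectory`.
#' @param path file path (`.rds`).
#' @return `path` invisibly (write) or the trajectory (read).
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- readRDS(path)
  stopifnot(inherits(tr, "cg_trajectory"))
  tr
}
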