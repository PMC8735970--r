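#' Read a model + protocol configuration document
#'
#' One YAML or JSON document describes a complete simulation: the model
#' `variant`, the `parameters` block (rate symbols as in
#' [ParameterSet-class], plus `NT` and optional `H0`), an optional
#' `protocol` list of `{t_start, t_end, param, value}` overrides (and
#' `{t, fraction}` bleach events under `bleaches`), and an optional
#' `initial_state` (named counts, or the string `"on-steady-state"`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List: `variant`, `params` ([ParameterSet]), `protocol`
#'   ([Protocol]), `init` (named counts or `"on"`).
#' @export
readModelConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$variant)) stop("config lacks a 'variant'")
  pars <- cfg$parameters
  NT <- if (!is.null(pars$NT)) pars$NT else 500
  H0 <- if (!is.null(pars$H0)) pars$H0 else NA_real_
  pars$NT <- NULL; pars$H0 <- NULL
  params <- paramSet(unlist(pars), NT = NT, H0 = H0)
  ov <- NULL
  if (!is.null(cfg$protocol) && length(cfg$protocol)) {
    pl <- cfg$protocol
    if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
    ov <- do.call(rbind, lapply(pl, function(o)
      data.frame(tStart = o$t_start, tEnd = o$t_end, param = o$param,
                 value = o$value, stringsAsFactors = FALSE)))
    rownames(ov) <- NULL
  }
  bl <- NULL
  if (!is.null(cfg$bleaches) && length(cfg$bleaches)) {
    bll <- cfg$bleaches
    if (is.data.frame(bll)) bll <- split(bll, seq_len(nrow(bll)))
    bl <- do.call(rbind, lapply(bll, function(o)
      data.frame(t = o$t, fraction = o$fraction)))
    rownames(bl) <- NULL
  }
  init <- cfg$initial_state
  init <- if (is.null(init) || identical(init, "on-steady-state")) "on"
          else unlist(init)
  list(variant = cfg$variant, params = params,
       protocol = protocol(ov, bl), init = init)
}

#' Write a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds the sample grid (column `t`) and one column per species;
#' the sidecar records the variant, seed, event count and protocol.
#'
#' @param traj A [Trajectory].
#' @param path CSV output path (sidecar at `<path>.json`).
#' @return The path, invisibly.
#' @export
writeTrajectoryCsv <- function(traj, path) {
  df <- data.frame(t = traj@times, traj@states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(variant = traj@variant, seed = traj@seed,
         eventCount = traj@eventCount, exit = traj@exit,
         overrides = traj@protocol@overrides,
         bleaches = traj@protocol@bleaches),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @param path CSV path written by [writeTrajectoryCsv()].
#' @export
readTrajectoryCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ov <- meta$overrides
  prot <- protocol(if (length(ov)) as.data.frame(ov) else NULL,
                   if (length(meta$bleaches)) as.data.frame(meta$bleaches)
                   else NULL)
  new("Trajectory", times = df$t,
      states = as.matrix(df[, -1, drop = FALSE]),
      variant = meta$variant, seed = meta$seed,
      eventCount = meta$eventCount, protocol = prot, exit = meta$exit)
}
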