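#' Write and read lung model configurations
#'
#' Configurations are JSON with keys `n`, `resistances_in` (list of
#' `[j, k, value]` triples), `resistances_ex` (triples, or a scalar `factor`
#' applied to the inspiratory tree), `compliance_in` / `compliance_ex`
#' (per-compartment blocks `a1, b1, a2, a3, b3, x1, x2, v_cap`; one block is
#' recycled), `beta_smooth`, and a `breath` block (`T_in`, `T_ex`, `V0`,
#' `VT`, `alpha1`, `alpha2`). The loader validates all model invariants and
#' names the offending key on failure.
#'
#' @param model a [lung_model()].
#' @param spec a [breath_spec()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `load_config` returns a
#'   list with `model` and `spec`.
#' @export
write_config <- function(model, spec, path) {
  tree_triples <- function(tree)
    do.call(rbind, lapply(0:tree$n, function(j)
      cbind(j, seq_len(2^j), tree$resistances[[j + 1L]])))
  curve_block <- function(cc)
    cc[c("a1", "b1", "a2", "a3", "b3", "x1", "x2", "v_cap")]
  cfg <- list(
    n = model$n,
    resistances_in = tree_triples(model$tree_in),
    resistances_ex = tree_triples(model$tree_ex),
    compliance_in = unname(lapply(model$compliance_in, curve_block)),
    compliance_ex = unname(lapply(model$compliance_ex, curve_block)),
    beta_smooth = model$compliance_in[[1]]$beta_smooth,
    breath = list(T_in = spec$T_in, T_ex = spec$T_ex, V0 = spec$V0,
                  VT = spec$VT, alpha1 = spec$alpha1, alpha2 = spec$alpha2))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config error: missing key '", key, "'")
    cfg[[key]]
  }
  n <- as.integer(need("n"))
  parse_tree <- function(triples, label) {
    triples <- as.matrix(triples)
    res <- lapply(0:n, function(j) rep(NA_real_, 2^j))
    for (r in seq_len(nrow(triples))) {
      j <- triples[r, 1]; k <- triples[r, 2]
      if (j < 0 || j > n || k < 1 || k > 2^j)
        stop("config error: ", label, " entry [", j, ",", k, "] out of range")
      res[[j + 1]][k] <- triples[r, 3]
    }
    for (j in 0:n) {
      miss <- which(is.na(res[[j + 1]]))
      if (length(miss))
        stop("config error: ", label, " missing entry [", j, ",", miss[1], "]")
    }
    airway_tree(n, res)
  }
  tree_in <- parse_tree(need("resistances_in"), "resistances_in")
  rex <- cfg$resistances_ex
  fac <- if (is.list(rex)) rex[["factor"]]
  else if (!is.null(names(rex))) unname(rex["factor"]) else NULL
  tree_ex <- if (!is.null(fac) && !is.na(fac)) scale_tree(tree_in, fac)
  else parse_tree(need("resistances_ex"), "resistances_ex")
  beta <- cfg$beta_smooth %||% 30
  parse_curves <- function(blocks, phase, label) {
    if (is.data.frame(blocks)) blocks <- split(blocks, seq_len(nrow(blocks)))
    else if (!is.null(blocks$a1)) blocks <- list(blocks)  # single block
    lapply(blocks, function(b)
      tryCatch(
        compliance_curve(b$a1, b$b1, b$a2, b$a3, b$b3, b$x1, b$x2, b$v_cap,
                         beta_smooth = beta, phase = phase),
        error = function(e) stop("config error in ", label, ": ",
                                 conditionMessage(e), call. = FALSE)))
  }
  model <- lung_model(tree_in, tree_ex,
                      parse_curves(need("compliance_in"), "inspiration",
                                   "compliance_in"),
                      parse_curves(need("compliance_ex"), "expiration",
                                   "compliance_ex"))
  b <- need("breath")
  spec <- breath_spec(b$T_in, b$T_ex, b$V0, b$VT,
                      alpha1 = b$alpha1 %||% 2.0, alpha2 = b$alpha2 %||% 0.1)
  list(model = model, spec = spec)
}

#' Export a trajectory, pressure trace or report
#'
#' `write_trajectory` writes the tidy long CSV (`time_s, compartment,
#' volume_l, flow_l_per_s, accel_l_per_s2, phase`); `read_trajectory` reads
#' it back into a tibble; `write_report` serializes any list/tibble bundle
#' to JSON.
#'
#' @param traj a `lung_trajectory` (or anything with a [tidy()] method
#'   producing the trajectory columns).
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- if (inherits(traj, "data.frame")) traj else tidy(traj)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_trajectory
#' @param report a list or tibble.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
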