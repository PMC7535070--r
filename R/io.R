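#' Look up a shipped fixture problem by id
#'
#' Ids: `"toxicology[:normal|:lognormal][:i]"` (`i` selects a single rival
#' pair), `"mm_mmm[:lognormal|:gamma]"`, `"trig_poly[:i]"`,
#' `"logistic4[:i]"`, `"cubic_vs_linear"`, `"constrained_quadratic"`,
#' `"dette:m"`.
#'
#' @param id Fixture id string.
#' @return A [discrim_pair], [discrim_set] or [stdmaximin_problem].
#' @export
fixture_problem <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  head <- parts[1]
  pick <- function(obj, k) {
    if (is.na(k)) obj else pair_from_set(obj, as.integer(k))
  }
  switch(head,
    toxicology = {
      err <- if (length(parts) >= 2 && parts[2] %in% c("normal", "lognormal"))
               parts[2] else "normal"
      k <- if (length(parts) >= 2 && !parts[2] %in% c("normal", "lognormal"))
             parts[2] else if (length(parts) >= 3) parts[3] else NA
      pick(toxicology_set(err), k)
    },
    mm_mmm = mm_mmm_pair(if (length(parts) >= 2) parts[2] else "lognormal"),
    trig_poly = pick(trig_poly_set(),
                     if (length(parts) >= 2) parts[2] else NA),
    logistic4 = pick(logistic4_set(),
                     if (length(parts) >= 2) parts[2] else NA),
    cubic_vs_linear = cubic_vs_linear_pair(),
    constrained_quadratic = constrained_quadratic_pair(),
    dette = dette_family(as.integer(parts[2])),
    stop("unknown fixture: ", id)
  )
}

#' Compile a mean-function expression string
#'
#' Expressions use `x` for the design variable and `theta[i]` (or named
#' scalars listed in `par_names`) for parameters, with arithmetic, `exp`,
#' `log`, `sqrt`, `sin`, `cos` and powers available.
#'
#' @keywords internal
compile_mean_expr <- function(expr_str, par_names) {
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "sin",
               "cos", "tan", "abs", "x", "theta", "[", "pi", par_names)
  e <- str2lang(expr_str)
  check <- function(node) {
    if (is.call(node)) {
      lapply(as.list(node), check)
    } else if (is.name(node)) {
      if (!as.character(node) %in% allowed)
        stop("disallowed symbol in model expression: ", as.character(node))
    }
    invisible(NULL)
  }
  check(e)
  function(x, theta) {
    env <- list2env(stats::setNames(as.list(theta), par_names),
                    parent = baseenv())
    env$x <- x; env$theta <- theta; env$pi <- pi
    eval(e, env)
  }
}

#' @keywords internal
parse_model_config <- function(mc, role = "rival") {
  if (is.null(mc$expr)) stop("model config is missing the key 'expr'")
  par_names <- if (!is.null(mc$parameters)) names(mc$parameters)
               else mc$par_names
  if (is.null(par_names))
    stop("model config needs 'parameters' (named bounds) or 'par_names'")
  fn <- compile_mean_expr(mc$expr, par_names)
  p <- length(par_names)
  ps <- NULL
  if (role == "rival") {
    get_bound <- function(nm, which, default) {
      b <- mc$parameters[[nm]][[which]]
      if (is.null(b)) default
      else if (identical(b, "Inf")) Inf
      else if (identical(b, "-Inf")) -Inf
      else as.numeric(b)
    }
    lower <- vapply(par_names, get_bound, numeric(1), "lower", -Inf)
    upper <- vapply(par_names, get_bound, numeric(1), "upper", Inf)
    slo <- vapply(par_names, get_bound, numeric(1), "sample_lower", NA_real_)
    shi <- vapply(par_names, get_bound, numeric(1), "sample_upper", NA_real_)
    if (all(is.na(slo))) slo <- NULL else
      slo <- ifelse(is.na(slo), ifelse(is.finite(lower), lower, -10), slo)
    if (all(is.na(shi))) shi <- NULL else
      shi <- ifelse(is.na(shi), ifelse(is.finite(upper), upper, 10), shi)
    ps <- param_space(lower, upper, slo, shi)
  }
  list(model = mean_model(fn, p, ps, name = mc$name %||% ""),
       nominal = if (!is.null(mc$nominal)) as.numeric(mc$nominal) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a discrimination problem from a YAML config file
#'
#' The config either names a shipped fixture (`fixture: toxicology`,
#' optional `error:` override applied via the fixture id) or specifies the
#' problem explicitly:
#' \preformatted{
#' error: normal            # normal | lognormal | gamma | binomial
#' space: {lower: 0, upper: 1250}
#' true_model:
#'   expr: "a*exp(-x/b)"
#'   par_names: [a, b]
#'   nominal: [4.282, 835.571]
#' rivals:
#'   - expr: "a"
#'     parameters:
#'       a: {lower: 0, upper: Inf, sample_lower: 0.1, sample_upper: 10}
#' }
#' A single entry under `rivals` yields a [discrim_pair]; several yield a
#' [discrim_set].  Expression models are smoke-tested at the nominal
#' parameters on a grid of the design space.
#'
#' @param path Config file path.
#' @return A [discrim_pair] or [discrim_set].
#' @export
load_problem <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$fixture)) {
    id <- cfg$fixture
    if (!is.null(cfg$error)) id <- paste(id, cfg$error, sep = ":")
    if (!is.null(cfg$pair)) id <- paste(id, cfg$pair, sep = ":")
    return(fixture_problem(id))
  }
  if (is.null(cfg$error)) stop("config is missing the key 'error'")
  if (is.null(cfg$space) || is.null(cfg$space$lower) ||
      is.null(cfg$space$upper))
    stop("config is missing 'space' with keys 'lower' and 'upper'")
  space <- design_space(as.numeric(cfg$space$lower),
                        as.numeric(cfg$space$upper))
  err <- error_model(cfg$error)
  if (is.null(cfg$true_model)) stop("config is missing the key 'true_model'")
  tm <- parse_model_config(cfg$true_model, role = "true")
  if (is.null(tm$nominal))
    stop("config key 'true_model' needs 'nominal' parameter values")
  if (is.null(cfg$rivals) || length(cfg$rivals) < 1L)
    stop("config is missing the key 'rivals'")
  rivals <- lapply(cfg$rivals, parse_model_config, role = "rival")
  if (length(rivals) == 1L)
    discrim_pair(tm$model, tm$nominal, rivals[[1]]$model, space, err)
  else
    discrim_set(tm$model, tm$nominal, lapply(rivals, `[[`, "model"),
                space, err)
}

#' Serialize a search result to JSON
#'
#' Schema: `design`, `value`/`efficiencies`, `theta_hat`, `alpha`,
#' `certificate` (verdict, max psi, argmax), `meta`.
#'
#' @param res A `pairwise_result`, `maxmin_result` or `stdmaximin_result`.
#' @param path Optional output file.
#' @param meta Optional named list stored under `meta`.
#' @export
result_to_json <- function(res, path = NULL, meta = NULL) {
  out <- list(design = list(support = res$design$support,
                            weights = res$design$weights))
  if (inherits(res, "pairwise_result")) {
    out$value <- res$criterion$value
    out$theta_hat <- res$criterion$theta_hat
    out$converged <- res$criterion$converged
  } else if (inherits(res, "maxmin_result")) {
    out$efficiencies <- res$profile$eff
    out$value <- res$profile$min_eff
    out$active_set <- res$profile$active_set
    if (!is.null(res$alpha)) out$alpha <- as.numeric(res$alpha)
  } else if (inherits(res, "stdmaximin_result")) {
    out$value <- res$value
    out$grid <- res$grid
    out$efficiencies <- res$profile
  }
  if (!is.null(res$certificate))
    out$certificate <- list(passed = res$certificate$passed,
                            max_psi = res$certificate$max_psi,
                            argmax_x = res$certificate$argmax_x)
  if (!is.null(meta)) out$meta <- meta
  txt <- jsonlite::toJSON(out, digits = I(15), auto_unbox = TRUE,
                          null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @keywords internal
cli_parse_flags <- function(args) {
  flags <- list()
  pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(cmd = if (length(pos)) pos[1] else NA_character_, flags = flags)
}

#' Command-line entry point
#'
#' Subcommands: `find` (pairwise search), `maxmin`, `stdmaximin`,
#' `evaluate` (criterion/efficiency of a given design), `certify`
#' (equivalence check of a given design), `benchmark` (replicated
#' comparison of search algorithms).  Problems come from `--config FILE`
#' (see [load_problem]) or `--fixture ID`; designs from `--design FILE`
#' (JSON or CSV).  Common flags: `--n-support`, `--swarm`, `--iters`,
#' `--seed`, `--restarts`, `--algorithm psoqn|fedorov|remes`, `--grid`,
#' `--tol`, `--out FILE`.
#'
#' Invoked by the installed `cli/discrimdesign` Rscript; callable directly
#' for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  p <- cli_parse_flags(args)
  if (is.na(p$cmd)) {
    message("usage: discrimdesign <find|maxmin|stdmaximin|evaluate|certify|benchmark> [flags]")
    return(invisible(1L))
  }
  f <- p$flags
  seed <- if (!is.null(f$seed)) as.integer(f$seed) else NULL
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  problem <- if (!is.null(f$config)) load_problem(f$config)
             else if (!is.null(f$fixture)) fixture_problem(f$fixture)
             else stop("supply --config FILE or --fixture ID")
  read_design <- function(key) {
    path <- f[[key]]
    if (is.null(path)) stop("supply --", key, " FILE")
    if (grepl("\\.csv$", path)) read_design_csv(path)
    else design_from_json(path)
  }
  pso <- pso_config(swarm = num(f$swarm, 32), iters = num(f$iters, 200),
                    seed = NULL)
  n_sup <- if (!is.null(f$n_support)) as.integer(f$n_support) else NULL
  restarts <- num(f$restarts, 4)
  tol <- num(f$tol, 1e-3)
  gsz <- num(f$grid, 1001)
  emit <- function(res, meta) {
    txt <- result_to_json(res, path = f$out, meta = meta)
    if (is.null(f$out)) cat(txt, "\n") else message("written: ", f$out)
  }
  status <- 0L
  switch(p$cmd,
    find = {
      alg <- f$algorithm %||% "psoqn"
      res <- switch(alg,
        psoqn = pso_qn(problem, n_support = n_sup, pso = pso,
                       restarts = restarts, seed = seed,
                       certify_tol = tol, grid_size = gsz),
        fedorov = fedorov_wynn(problem, n_support = n_sup,
                               iterations = pso$iters, seed = seed,
                               restarts = restarts),
        remes = remes(problem, n_support = n_sup, iterations = pso$iters,
                      seed = seed, restarts = restarts),
        stop("unknown --algorithm: ", alg))
      message(sprintf("criterion %.6g  certificate %s", res$criterion$value,
                      if (is.null(res$certificate)) "n/a"
                      else if (res$certificate$passed) "passed" else "FAILED"))
      emit(res, list(cmd = "find", algorithm = alg, seed = seed))
    },
    maxmin = {
      stopifnot(inherits(problem, "discrim_set"))
      refs <- lapply(seq_along(problem$rivals), function(i)
        pso_qn(pair_from_set(problem, i), n_support = n_sup, pso = pso,
               restarts = restarts,
               seed = if (is.null(seed)) NULL else seed + i))
      res <- pso_s_qn(problem, refs, n_support = n_sup,
                      pso = pso_config(swarm = pso$swarm,
                                       iters = 2L * pso$iters),
                      restarts = restarts, seed = seed, certify_tol = tol)
      message(sprintf("min efficiency %.4f", res$profile$min_eff))
      emit(res, list(cmd = "maxmin", seed = seed))
    },
    stdmaximin = {
      stopifnot(inherits(problem, "stdmaximin_problem"))
      res <- nested_pso_qn(problem, n_support = num(f$n_support, 3),
                           outer = pso, grid_size = num(f$tr_grid, 21),
                           restarts = restarts, seed = seed)
      message(sprintf("worst-case efficiency %.4f", res$value))
      emit(res, list(cmd = "stdmaximin", seed = seed))
    },
    evaluate = {
      stopifnot(inherits(problem, "discrim_pair"))
      d <- read_design("design")
      if (!is.null(seed)) set.seed(seed)
      cv <- inner_minimize(problem, d, restarts = restarts)
      out <- list(value = cv$value, theta_hat = cv$theta_hat)
      if (!is.null(f$reference)) {
        ref <- if (grepl("\\.csv$", f$reference)) read_design_csv(f$reference)
               else design_from_json(f$reference)
        out$efficiency <- efficiency(problem, d, ref, restarts = restarts)
        message(sprintf("criterion %.6g  efficiency %.4f", out$value,
                        out$efficiency))
      } else message(sprintf("criterion %.6g", out$value))
      txt <- jsonlite::toJSON(out, digits = I(15), auto_unbox = TRUE)
      if (is.null(f$out)) cat(as.character(txt), "\n")
      else writeLines(as.character(txt), f$out)
    },
    certify = {
      stopifnot(inherits(problem, "discrim_pair"))
      d <- read_design("design")
      if (!is.null(seed)) set.seed(seed)
      rep_ <- equivalence_check(problem, d, grid_size = gsz, tol = tol)
      print(rep_)
      out <- list(passed = rep_$passed, max_psi = rep_$max_psi,
                  argmax_x = rep_$argmax_x)
      txt <- jsonlite::toJSON(out, digits = I(15), auto_unbox = TRUE)
      if (is.null(f$out)) cat(as.character(txt), "\n")
      else writeLines(as.character(txt), f$out)
    },
    benchmark = {
      stopifnot(inherits(problem, "discrim_pair"))
      reps <- num(f$reps, 10)
      ref <- if (!is.null(f$reference)) {
        if (grepl("\\.csv$", f$reference)) read_design_csv(f$reference)
        else design_from_json(f$reference)
      } else pso_qn(problem, n_support = n_sup, pso = pso,
                    restarts = restarts, seed = seed)$design
      if (!is.null(seed)) set.seed(seed)
      refv <- inner_minimize(problem, ref, restarts = restarts + 4)$value
      algs <- c("psoqn", "fedorov",
                if (problem$error$tag == "normal") "remes")
      rows <- do.call(rbind, lapply(algs, function(alg) {
        effs <- vapply(seq_len(reps), function(r) {
          res <- try(switch(alg,
            psoqn = pso_qn(problem, n_support = n_sup, pso = pso,
                           restarts = restarts),
            fedorov = fedorov_wynn(problem, n_support = n_sup,
                                   iterations = pso$iters,
                                   restarts = restarts),
            remes = remes(problem, n_support = n_sup,
                          iterations = pso$iters, restarts = restarts)),
            silent = TRUE)
          if (inherits(res, "try-error")) return(NA_real_)
          min(res$criterion$value / refv, 1)
        }, numeric(1))
        data.frame(algorithm = alg, reps = reps,
                   min_eff = min(effs, na.rm = TRUE),
                   max_eff = max(effs, na.rm = TRUE),
                   n_90 = sum(effs >= 0.9, na.rm = TRUE),
                   n_fail = sum(is.na(effs)))
      }))
      if (is.null(f$out)) print(rows)
      else { utils::write.csv(rows, f$out, row.names = FALSE)
             message("written: ", f$out) }
    },
    stop("unknown command: ", p$cmd)
  )
  invisible(status)
}
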