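## End-to-end drivers: sequential and parallel power posterior analyses,
## bit-exact TSV sample files, run manifests with resume, the flat key=value
## config format, and the expected-runtime model for M CPUs.

worker_seed <- function(seed, w) {
  # deterministic, distinct per worker, kept inside 32-bit integer range
  as.integer((as.numeric(seed) + 48611 * as.numeric(w)) %% 2147483629 + 1)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write per-stone samples to the bit-exact TSV format
#'
#' UTF-8 TSV with header \code{stone power iteration log_likelihood}; power
#' and log likelihood printed with 17 significant digits (lossless for
#' doubles); rows grouped by stone in decreasing power order.
#'
#' @param stones list of \code{stone_samples} (decreasing power order).
#' @param path output file.
#' @export
write_samples <- function(stones, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("stone\tpower\titeration\tlog_likelihood", con)
  for (st in stones) {
    writeLines(sprintf("%d\t%s\t%d\t%s", st$stone, fmt17(st$power),
                       st$iterations, fmt17(st$loglik)), con)
  }
  invisible(path)
}

#' Read a per-stone sample TSV
#'
#' @param path file written by \code{\link{write_samples}}.
#' @return data.frame with columns stone, power, iteration, log_likelihood.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("integer", "numeric",
                                         "integer", "numeric"))
  expected <- c("stone", "power", "iteration", "log_likelihood")
  if (!identical(names(df), expected))
    stop("sample file '", path, "' does not have the expected header ",
         paste(expected, collapse = "/"), call. = FALSE)
  df
}

#' Merge per-worker sample files into a sample matrix
#'
#' Validates that the files jointly cover every stone index 0..K-1 exactly
#' once with a common per-stone sample count, then assembles the
#' \code{\link{sample_matrix}} for the estimators.
#'
#' @param paths character vector of sample TSV paths.
#' @return a \code{\link{sample_matrix}}.
#' @export
merge_samples <- function(paths) {
  df <- do.call(rbind, lapply(paths, read_samples))
  stones <- sort(unique(df$stone))
  K <- length(stones)
  if (!identical(stones, 0:(K - 1L)))
    stop("sample files do not cover stones 0..K-1; missing: ",
         paste(setdiff(0:max(stones), stones), collapse = ", "),
         call. = FALSE)
  counts <- table(df$stone)
  if (length(unique(as.integer(counts))) != 1L)
    stop("unequal sample counts across stones", call. = FALSE)
  n <- as.integer(counts[1])
  powers <- numeric(K)
  samples <- matrix(NA_real_, K, n)
  for (k in stones) {
    rows <- df[df$stone == k, ]
    pw <- unique(rows$power)
    if (length(pw) != 1L)
      stop("stone ", k, " appears with multiple powers", call. = FALSE)
    powers[k + 1L] <- pw
    samples[k + 1L, ] <- rows$log_likelihood[order(rows$iteration)]
  }
  sample_matrix(powers, samples)
}

# run one worker's block, recording per-stone RNG state and entry values so
# an interrupted run can be resumed stone by stone
worker_run <- function(model, stones, powers, config, wseed,
                       sample_path = NULL, init_state = NULL) {
  set.seed(wseed)
  state <- if (is.null(init_state)) {
    pre_burnin(model, config, beta_target = powers[1])
  } else init_state
  out <- vector("list", length(stones))
  records <- vector("list", length(stones))
  for (i in seq_along(stones)) {
    records[[i]] <- list(stone = stones[i], power = powers[i],
                         rng_state = .Random.seed,
                         init_values = state$values)
    out[[i]] <- run_stone(model, powers[i], state, config, stone = stones[i])
    state <- out[[i]]$final_state
    if (!is.null(sample_path))
      write_samples(out[seq_len(i)], sample_path)  # partial file for resume
  }
  list(stones = out, records = records)
}

#' Run a full power posterior analysis sequentially
#'
#' One pre-burn-in at the posterior (beta = 1), then all K stones from
#' posterior to prior with chain-state carry-over. Equivalent to (and
#' implemented as) the parallel runner with a single worker.
#'
#' @param model a \code{\link{pp_model}}.
#' @param schedule a \code{\link{make_powers}} schedule.
#' @param config a \code{\link{stone_run_config}}.
#' @param output_dir directory for sample files and the run manifest
#'   (created if needed); NULL keeps everything in memory.
#' @return a \code{\link{sample_matrix}}.
#' @export
run_sequential <- function(model, schedule, config, output_dir = NULL) {
  run_parallel(model, schedule, config, M = 1L, N = 1L,
               output_dir = output_dir, backend = "serial")
}

#' Run a power posterior analysis over M parallel workers
#'
#' Stones are partitioned into M consecutive blocks
#' (\code{\link{partition_blocks}}); each worker independently pre-burns at
#' its block's first power and runs its block, with no communication until
#' the single barrier at the end, where the master merges all samples. Worker
#' w uses an RNG stream derived deterministically from (seed, w), so the
#' multi-process backend is bit-identical to the in-process serial emulation
#' of the same block plan -- and a single-worker run is bit-identical to
#' \code{\link{run_sequential}}.
#'
#' @param model a \code{\link{pp_model}}.
#' @param schedule a \code{\link{make_powers}} schedule.
#' @param config a \code{\link{stone_run_config}}.
#' @param M worker count (1 <= M <= K).
#' @param N CPUs per likelihood evaluation (forwarded to models built with
#'   site-partitioned likelihoods; numerically identical for any N).
#' @param output_dir directory for per-worker sample files
#'   (\code{samples_worker<w>.tsv}), the merged \code{samples_all.tsv} and
#'   \code{manifest.json}; NULL keeps everything in memory.
#' @param backend \code{"multiprocess"} (forked workers via the parallel
#'   package) or \code{"serial"} (in-process emulation of the same plan).
#' @return a \code{\link{sample_matrix}}; the block plan and per-stone
#'   acceptance rates are attached as attributes \code{"plan"} and
#'   \code{"acceptance"}.
#' @export
run_parallel <- function(model, schedule, config, M = 1L, N = 1L,
                         output_dir = NULL,
                         backend = c("multiprocess", "serial")) {
  backend <- match.arg(backend)
  stopifnot(inherits(schedule, "power_schedule"),
            inherits(config, "stone_run_config"))
  plan <- partition_blocks(schedule, M, N)
  asc <- rev(schedule$powers)               # beta_k by 0-based stone index k
  if (!is.null(output_dir) &&
      !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  paths <- if (is.null(output_dir)) vector("list", M) else
    file.path(output_dir, sprintf("samples_worker%d.tsv", seq_len(M)))
  job <- function(m) {
    worker_run(model,
               stones = plan$blocks[[m]],
               powers = asc[plan$blocks[[m]] + 1L],
               config = config,
               wseed = worker_seed(config$seed, m),
               sample_path = if (is.null(output_dir)) NULL else paths[[m]])
  }
  results <- if (backend == "multiprocess" && M > 1L) {
    parallel::mclapply(seq_len(M), job, mc.cores = M, mc.set.seed = FALSE)
  } else {
    lapply(seq_len(M), job)
  }
  failed <- vapply(results, function(r)
    !is.list(r) || is.null(r$stones), TRUE)
  if (any(failed))
    stop("worker failure; incomplete stone indices: ",
         paste(unlist(plan$blocks[failed]), collapse = ", "),
         "; partial sample files retained", call. = FALSE)
  all_stones <- do.call(c, lapply(results, `[[`, "stones"))
  if (!is.null(output_dir)) {
    write_samples(all_stones, file.path(output_dir, "samples_all.tsv"))
    write_manifest(file.path(output_dir, "manifest.json"),
                   model, schedule, config, plan, results, paths)
  }
  sm <- stones_to_matrix(all_stones)
  attr(sm, "plan") <- plan
  attr(sm, "acceptance") <- lapply(all_stones, `[[`, "acceptance")
  sm
}

stones_to_matrix <- function(all_stones) {
  idx <- vapply(all_stones, `[[`, 0L, "stone")
  powers <- vapply(all_stones, `[[`, 0, "power")
  ord <- order(idx)
  samples <- do.call(rbind, lapply(all_stones[ord], `[[`, "loglik"))
  sample_matrix(powers[ord], samples)
}

write_manifest <- function(path, model, schedule, config, plan, results,
                           paths) {
  stones <- list()
  for (m in seq_along(results)) {
    for (rec in results[[m]]$records) {
      stones[[length(stones) + 1L]] <- list(
        stone = rec$stone, power = fmt17(rec$power), worker = m,
        file = if (is.null(paths[[m]])) NA else basename(paths[[m]]),
        completed = TRUE,
        rng_state = rec$rng_state,
        # doubles as 17-significant-digit strings: lossless round trip
        init_values = lapply(rec$init_values, fmt17))
    }
  }
  manifest <- list(
    model = model$name,
    config = unclass(config),
    K = schedule$K, alpha = schedule$alpha,
    M = plan$M, N = plan$N,
    blocks = plan$blocks,
    stones = stones)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Resume an interrupted analysis from its manifest
#'
#' Re-runs only the stones whose completion flags are false, restoring each
#' stone's recorded RNG state and entry parameter values, so the completed
#' run is bit-identical to an uninterrupted one.
#'
#' @param model the \code{\link{pp_model}} of the original run.
#' @param manifest_path path to \code{manifest.json}.
#' @param output_dir directory holding the sample files.
#' @return a \code{\link{sample_matrix}} over all K stones.
#' @export
resume <- function(model, manifest_path, output_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  config <- do.call(stone_run_config, man$config[c("L", "T", "burnin_frac",
                                                   "preburn_iters", "seed")])
  out <- vector("list", length(man$stones))
  for (i in seq_along(man$stones)) {
    rec <- man$stones[[i]]
    rec$power <- as.numeric(rec$power)
    rec$stone <- as.integer(rec$stone)
    if (isTRUE(rec$completed)) {
      df <- read_samples(file.path(output_dir, rec$file))
      rows <- df[df$stone == rec$stone, ]
      out[[i]] <- structure(list(stone = rec$stone, power = rec$power,
                                 loglik = rows$log_likelihood[order(rows$iteration)],
                                 iterations = sort(rows$iteration),
                                 final_state = NULL, acceptance = NULL),
                            class = "stone_samples")
    } else {
      assign(".Random.seed", as.integer(rec$rng_state), envir = globalenv())
      vals <- lapply(rec$init_values, function(v) as.numeric(unlist(v)))
      state <- new_state(model, vals, compute_ll = rec$power > 0)
      out[[i]] <- run_stone(model, rec$power, state, config,
                            stone = rec$stone)
    }
  }
  stones_to_matrix(out)
}

#' Expected runtime of a parallel power posterior analysis
#'
#' With M CPUs each worker runs at most \eqn{\lceil K/M \rceil} power
#' posterior simulations plus its own pre-burn-in (which costs about one
#' simulation), out of K + 1 simulation-equivalents for the single-CPU run:
#' \deqn{E[t_M] = t_1 \times \frac{\lceil K/M \rceil + 1}{K + 1}.}
#'
#' @param t1 measured single-CPU runtime (seconds).
#' @param K number of power posterior simulations.
#' @param M CPU count.
#' @return expected runtime in seconds.
#' @export
expected_runtime <- function(t1, K, M) {
  stopifnot(t1 > 0, K >= 1, M >= 1)
  t1 * (ceiling(K / M) + 1) / (K + 1)
}

#' Read a flat key = value run configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored; unknown keys are errors. Recognised keys: model, stones, alpha,
#' iterations, thinning, burnin_frac, preburn_iters, seed, workers,
#' cpus_per_likelihood, alignment, tree, output_dir.
#'
#' @param path config file path.
#' @return named list of typed values.
#' @export
read_run_config <- function(path) {
  known <- c(model = "character", stones = "integer", alpha = "numeric",
             iterations = "integer", thinning = "integer",
             burnin_frac = "numeric", preburn_iters = "integer",
             seed = "integer", workers = "integer",
             cpus_per_likelihood = "integer", alignment = "character",
             tree = "character", output_dir = "character")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L)
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    key <- kv[2]; val <- trimws(kv[3])
    if (!key %in% names(known))
      stop("unknown config key: '", key, "'", call. = FALSE)
    out[[key]] <- switch(known[[key]],
                         integer = as.integer(val),
                         numeric = as.numeric(val),
                         val)
  }
  out
}
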