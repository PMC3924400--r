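#' Split an instance into independent subproblems
#'
#' The search decomposes into one job per window of the first sequence:
#' job `k` anchors the stack on the first-sequence l-mer starting at `k`.
#' The deduplicated union of the job outputs equals the serial output.
#'
#' @param instance A [motif_instance()].
#' @param l Motif length.
#' @return A list of jobs, each `list(first_offset = <1-based start>)`.
#' @export
split_jobs <- function(instance, l) {
  stopifnot(inherits(instance, "motif_instance"))
  if (instance$lengths[1L] < l) stop("first sequence shorter than l")
  lapply(seq_len(instance$lengths[1L] - l + 1L),
         function(k) list(first_offset = k))
}

# search restricted to a subset of first-row window starts (1-based)
pms8_search_offsets <- function(instance, l, d, params, offsets) {
  rp <- resolve_params(instance, l, d, params)
  codes <- encode_instance(instance)
  cpp_pms8_search(codes, l, d, instance$alphabet$size, rp$t, rp$n_prime,
                  params$sort_rows, params$pair_table, params$packing,
                  params$minimal_filter, as.integer(offsets) - 1L)
}

#' Parallel motif search over a dynamic work queue
#'
#' Runs the per-window subproblems of [split_jobs()] on a pool of forked
#' worker processes with dynamic dispatch (each idle worker pulls the next
#' job), which keeps workers busy even though subproblem runtimes vary
#' wildly with neighborhood sizes. Results are merged, deduplicated and
#' sorted, so the output is identical to the serial search for any worker
#' count and independent of job completion order. A failed job is retried
#' once; a second failure is an error.
#'
#' @param instance A [motif_instance()].
#' @param l Motif length.
#' @param d Distance budget.
#' @param params A [pms8_params()].
#' @param workers Number of worker processes (`>= 1`).
#' @param positions Also report witness positions (see [pms8_search()]).
#' @return A `motif_result`, identical to the serial search.
#' @export
run_parallel_search <- function(instance, l, d, params = pms8_params(),
                                workers = 1L, positions = FALSE) {
  stopifnot(inherits(instance, "motif_instance"))
  workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be at least 1")
  if (any(instance$lengths < l)) stop("every sequence must be at least l long")
  if (d > l || d < 0) stop("d must be in [0, l]")
  jobs <- split_jobs(instance, l)
  run_one <- function(job) {
    pms8_search_offsets(instance, l, d, params, job$first_offset)
  }
  if (workers == 1L) {
    outs <- lapply(jobs, run_one)
  } else {
    outs <- parallel::mclapply(jobs, function(job) try(run_one(job), silent = TRUE),
                               mc.cores = workers, mc.preschedule = FALSE)
    failed <- vapply(outs, function(o) inherits(o, "try-error"), logical(1))
    if (any(failed)) {
      # one retry per failed job, then give up
      for (i in which(failed)) {
        outs[[i]] <- tryCatch(run_one(jobs[[i]]),
                              error = function(e)
                                stop(sprintf("job %d failed twice: %s", i,
                                             conditionMessage(e))))
      }
    }
  }
  mm <- do.call(rbind, lapply(outs, `[[`, "motifs"))
  if (is.null(mm)) mm <- matrix(integer(0), 0, l)
  rp <- resolve_params(instance, l, d, params)
  build_motif_result(mm, instance, l, d,
                     stats = list(
                       tuples_explored = sum(vapply(outs, `[[`, numeric(1),
                                                    "tuples_explored")),
                       neighborhoods_generated = sum(vapply(outs, `[[`, numeric(1),
                                                            "neighborhoods_generated")),
                       candidates_verified = sum(vapply(outs, `[[`, numeric(1),
                                                        "candidates_verified")),
                       threshold_t = rp$t, n_prime = rp$n_prime,
                       jobs = length(jobs), workers = workers),
                     positions = positions)
}
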