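#' Write / read trial logs
#'
#' The trial-log CSV has one row per trial with header
#' `subject_id,block,trial,stimulus,response,feedback`: stimulus as 1-based
#' integer, response as its key label (d/f/k/l), feedback 0/1. The
#' companion mappings CSV (`subject_id,block,s1,s2,s3,s4`) gives each
#' block's true mapping as response labels. Reading validates the schema
#' and checks every row's feedback against the deterministic feedback rule,
#' reporting offending rows by number.
#'
#' @param data An `srl_data` dataset.
#' @param path Output CSV path.
#' @return `write_trial_log`/`write_mappings` invisibly return `path`;
#'   `read_trial_log` returns an `srl_data`.
#' @export
write_trial_log <- function(data, path) {
  stopifnot(inherits(data, "srl_data"))
  cfg <- data$config
  rows <- lapply(data$subjects, function(subject) {
    do.call(rbind, lapply(subject$blocks, function(b) {
      data.frame(subject_id = subject$subject_id, block = b$block_id,
                 trial = seq_along(b$stimulus), stimulus = b$stimulus,
                 response = cfg$response_labels[b$response],
                 feedback = b$feedback, stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
write_mappings <- function(data, path) {
  stopifnot(inherits(data, "srl_data"))
  cfg <- data$config
  rows <- lapply(data$subjects, function(subject) {
    do.call(rbind, lapply(subject$blocks, function(b) {
      m <- as.data.frame(t(cfg$response_labels[b$mapping]))
      names(m) <- paste0("s", seq_along(b$mapping))
      cbind(data.frame(subject_id = subject$subject_id, block = b$block_id,
                       stringsAsFactors = FALSE), m)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @param trials_path,mappings_path Paths to the two CSVs.
#' @param config A [task_config()].
#' @export
read_trial_log <- function(trials_path, mappings_path,
                           config = task_config()) {
  tr <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  mp <- utils::read.csv(mappings_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "block", "trial", "stimulus", "response", "feedback")
  if (!identical(names(tr), need))
    stop("trial log header must be: ", paste(need, collapse = ","))
  scols <- paste0("s", seq_len(config$n_stimuli))
  if (!identical(names(mp), c("subject_id", "block", scols)))
    stop("mappings header must be: subject_id,block,",
         paste(scols, collapse = ","))
  bad <- which(!(tr$stimulus %in% seq_len(config$n_stimuli)))
  if (length(bad)) stop("invalid stimulus at trial-log row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(tr$response %in% config$response_labels))
  if (length(bad)) stop("invalid response label at trial-log row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(tr$feedback %in% c(0L, 1L)))
  if (length(bad)) stop("invalid feedback at trial-log row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  tr$response_idx <- response_index(tr$response, config)
  subjects <- lapply(unique(tr$subject_id), function(sid) {
    ts <- tr[tr$subject_id == sid, ]
    blocks <- lapply(sort(unique(ts$block)), function(bid) {
      tb <- ts[ts$block == bid, ]
      tb <- tb[order(tb$trial), ]
      if (!identical(tb$trial, seq_len(nrow(tb))))
        stop(sprintf("subject %s block %d: trial indices not consecutive",
                     sid, bid))
      mrow <- mp[mp$subject_id == sid & mp$block == bid, scols]
      if (nrow(mrow) != 1L)
        stop(sprintf("subject %s block %d: no unique mapping row", sid, bid))
      mapping <- response_index(as.character(unlist(mrow)), config)
      exp_fb <- as.integer(mapping[tb$stimulus] == tb$response_idx)
      bad <- which(tb$feedback != exp_fb)
      if (length(bad))
        stop(sprintf(
          "feedback inconsistent with mapping: subject %s block %d trial(s) %s",
          sid, bid, paste(tb$trial[bad], collapse = ", ")))
      new_block(bid, mapping, tb$stimulus, tb$response_idx, tb$feedback)
    })
    srl_subject(sid, blocks)
  })
  srl_data(subjects, config)
}

#' Write fit results to CSV
#'
#' One row per subject x model: fitted parameters, per-block
#' log-likelihoods and the total.
#'
#' @param fit An [fit_models()] result.
#' @param path Output CSV path.
#' @export
write_fits <- function(fit, path) {
  stopifnot(inherits(fit, "srl_fit"))
  llb <- do.call(rbind, lapply(names(fit$ll_blocks), function(id) {
    m <- fit$ll_blocks[[id]]
    d <- as.data.frame(m)
    names(d) <- paste0("ll_", colnames(m))
    d$subject_id <- id
    d$model <- rownames(m)
    d
  }))
  out <- merge(fit$fits, llb, by = c("subject_id", "model"), sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write assignment results to CSV
#'
#' One row per subject: the assigned label plus one column per performed
#' test's p-value (NA where a stage was not reached).
#'
#' @param assignment An [assign_subjects()] result.
#' @param path Output CSV path.
#' @export
write_assignments <- function(assignment, path) {
  stopifnot(inherits(assignment, "srl_assignment"))
  all_tests <- unique(unlist(lapply(assignment$p_values, names)))
  pv <- t(vapply(assignment$p_values, function(p) {
    out <- setNames(rep(NA_real_, length(all_tests)), all_tests)
    out[names(p)] <- p
    out
  }, numeric(length(all_tests))))
  colnames(pv) <- gsub(">", "_gt_", all_tests, fixed = TRUE)
  out <- cbind(assignment$labels, as.data.frame(pv))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
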