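#' Build per-sample candidate sets by sex/species exclusion
#'
#' A registry individual is a candidate for a sample iff its recorded sex
#' matches the sample's inferred sex (an undetermined sex call matches both)
#' and its recorded species matches the inferred species (an "admixed"
#' species call matches nobody and is flagged).
#'
#' @param evidence Data frame with columns \code{biosample},
#'   \code{sex_call} ("male"/"female"/"undetermined") and
#'   \code{species_call}.
#' @param registry Data frame with columns \code{name}, \code{sex},
#'   \code{species} (one row per candidate individual).
#' @return Named list of character vectors (candidate names per biosample);
#'   empty sets mark the sample unresolvable at this stage.
#' @export
candidate_sets <- function(evidence, registry) {
  stopifnot(all(c("biosample", "sex_call", "species_call") %in% names(evidence)),
            all(c("name", "sex", "species") %in% names(registry)))
  out <- vector("list", nrow(evidence))
  names(out) <- evidence$biosample
  for (i in seq_len(nrow(evidence))) {
    sx <- evidence$sex_call[i]
    sp <- evidence$species_call[i]
    ok_sex <- if (sx == "undetermined") rep(TRUE, nrow(registry))
              else registry$sex == sx
    ok_sp <- if (identical(sp, "admixed")) rep(FALSE, nrow(registry))
             else registry$species == sp
    out[[i]] <- registry$name[ok_sex & ok_sp]
  }
  out
}

#' Confirm candidates by kinship against pedigree expectations
#'
#' A candidate c is confirmed for sample s iff some kinship hit links s to a
#' known relative r of c with \code{phi_hat > floor} and
#' \code{|phi_hat - phi_exp(c, r)| <= tau}.  If passing hits support more
#' than one candidate of the sample's exclusion set, none is confirmed
#' (ambiguous, flagged).
#'
#' @param candidates Output of \code{\link{candidate_sets}}.
#' @param hits Data frame of kinship hits: \code{biosample},
#'   \code{relative}, \code{phi_hat}.
#' @param links Registry pedigree links: \code{candidate}, \code{relative},
#'   \code{phi_exp}.
#' @param tau Tolerance on |phi_hat - phi_exp| (default 0.1).
#' @param floor Background kinship floor (default 0.02).
#' @return Named list per biosample: \code{confirmed} (name or NA),
#'   \code{supported} (all candidates with a passing hit), \code{ambiguous}.
#' @export
kinship_confirm <- function(candidates, hits, links, tau = 0.1, floor = 0.02) {
  stopifnot(tau > 0, floor >= 0)
  if (nrow(hits) && length(bad <- setdiff(hits$relative, links$relative))) {
    stop("kinship hit references unknown relative(s): ",
         paste(unique(bad), collapse = ", "))
  }
  lapply(stats::setNames(names(candidates), names(candidates)), function(s) {
    cand <- candidates[[s]]
    h <- hits[hits$biosample == s & hits$phi_hat > floor, , drop = FALSE]
    supported <- character(0)
    for (cc in cand) {
      lk <- links[links$candidate == cc, , drop = FALSE]
      if (!nrow(lk)) next
      mm <- merge(h, lk, by = "relative")
      if (nrow(mm) && any(abs(mm$phi_hat - mm$phi_exp) <= tau)) {
        supported <- c(supported, cc)
      }
    }
    list(confirmed = if (length(supported) == 1L) supported else NA_character_,
         supported = supported,
         ambiguous = length(supported) > 1L)
  })
}

#' Assign corrected identities with global uniqueness
#'
#' Per sample, the intersection of the exclusion set, the kinship-confirmed
#' candidate (when present) and the records-channel candidate (when present)
#' is formed; channels that disagree (an empty intersection from non-empty
#' channels) flag the sample as \code{conflict}.  Samples whose intersection
#' is a singleton are assigned first (iterating, since each assignment
#' removes its individual from the other sets); remaining samples are
#' assigned by maximum bipartite matching restricted to their intersections,
#' and only where the matched partner is forced (every maximum matching
#' agrees).  Samples still ambiguous are \code{unresolved}.  No individual
#' is ever assigned to two samples.
#'
#' @param candidates Output of \code{\link{candidate_sets}}.
#' @param confirmations Output of \code{\link{kinship_confirm}} (or NULL to
#'   skip the kinship channel).
#' @param records Optional data frame \code{biosample},
#'   \code{records_candidate} (NA where the archival channel is silent).
#' @return Data frame per biosample: \code{assigned} (name or NA),
#'   \code{flag} in full-concordance/partial/conflict/unresolved, and the
#'   per-channel verdict columns.
#' @export
assign_identities <- function(candidates, confirmations = NULL,
                              records = NULL) {
  samples <- names(candidates)
  rec <- stats::setNames(rep(NA_character_, length(samples)), samples)
  if (!is.null(records)) {
    rec[records$biosample] <- as.character(records$records_candidate)
  }
  conf <- stats::setNames(rep(NA_character_, length(samples)), samples)
  ambig <- stats::setNames(rep(FALSE, length(samples)), samples)
  if (!is.null(confirmations)) {
    conf[names(confirmations)] <- vapply(confirmations, `[[`, "", "confirmed")
    ambig[names(confirmations)] <- vapply(confirmations, `[[`, TRUE, "ambiguous")
  }
  inter <- list(); flag <- stats::setNames(rep(NA_character_, length(samples)), samples)
  for (s in samples) {
    set <- candidates[[s]]
    conflict <- FALSE
    if (!is.na(conf[s])) {
      if (conf[s] %in% set) set <- conf[s] else conflict <- TRUE
    }
    if (!is.na(rec[s])) {
      if (rec[s] %in% set) set <- rec[s] else conflict <- TRUE
    }
    if (conflict) { flag[s] <- "conflict"; set <- character(0) }
    inter[[s]] <- sort(set)
  }
  assigned <- stats::setNames(rep(NA_character_, length(samples)), samples)
  active <- samples[is.na(flag)]
  # iterative singleton propagation (deterministic: lexicographic order)
  repeat {
    changed <- FALSE
    for (s in sort(active)) {
      if (!is.na(assigned[s])) next
      set <- setdiff(inter[[s]], assigned)
      if (length(set) == 1L) {
        if (set %in% assigned) next
        taken_by <- names(assigned)[!is.na(assigned) & assigned == set]
        if (length(taken_by)) next
        assigned[s] <- set
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # bipartite matching for the rest, accepting only forced partners
  rest <- active[is.na(assigned[active])]
  rest <- rest[vapply(rest, function(s) {
    length(setdiff(inter[[s]], assigned)) > 0L
  }, TRUE)]
  if (length(rest)) {
    cand_left <- sort(unique(setdiff(unlist(inter[rest]), assigned)))
    match0 <- bipartite_assign(rest, cand_left,
                               lapply(inter[rest], setdiff, y = assigned))
    for (s in names(match0)) {
      partner <- match0[[s]]
      if (is.na(partner)) next
      # forced iff removing the edge reduces the maximum matching size
      pruned <- lapply(inter[rest], setdiff, y = assigned)
      pruned[[s]] <- setdiff(pruned[[s]], partner)
      alt <- bipartite_assign(rest, cand_left, pruned)
      if (sum(!is.na(unlist(alt))) < sum(!is.na(unlist(match0)))) {
        assigned[s] <- partner
      }
    }
  }
  for (s in samples) {
    if (!is.na(flag[s])) next
    if (is.na(assigned[s])) { flag[s] <- "unresolved"; next }
    channels_agree <- (is.na(conf[s]) || conf[s] == assigned[s]) &&
      (is.na(rec[s]) || rec[s] == assigned[s])
    n_channels <- 1L + !is.na(conf[s]) + !is.na(rec[s])
    flag[s] <- if (!channels_agree) "conflict"
               else if (n_channels >= 2L && !ambig[s]) "full-concordance"
               else "partial"
  }
  data.frame(biosample = samples,
             assigned = unname(assigned),
             flag = unname(flag),
             sex_species_set = vapply(candidates, paste, "", collapse = ","),
             kinship_confirmed = unname(conf),
             records_candidate = unname(rec),
             stringsAsFactors = FALSE)
}

# maximum bipartite matching via igraph; returns named list sample -> partner
bipartite_assign <- function(samples, cands, sets) {
  edges <- character(0)
  for (s in samples) for (cc in sets[[s]]) edges <- c(edges, s, cc)
  if (!length(edges)) {
    return(stats::setNames(as.list(rep(NA_character_, length(samples))), samples))
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(samples) + length(cands),
                            name = c(samples, cands),
                            type = c(rep(FALSE, length(samples)),
                                     rep(TRUE, length(cands))))
  g <- igraph::add_edges(g, match(edges, c(samples, cands)))
  mm <- igraph::max_bipartite_match(g)$matching
  out <- as.list(mm[samples])
  lapply(out, function(x) if (is.na(x)) NA_character_ else unname(x))
}

#' Summarize discrepancies between reported and corrected identities
#'
#' @param assignment Output of \code{\link{assign_identities}}.
#' @param reported Data frame of reported metadata: \code{biosample},
#'   \code{lab_id}, \code{name}, \code{sex}.
#' @param registry Registry data frame (\code{name}, \code{sex}, ...).
#' @param records_lab_ids Optional data frame \code{biosample},
#'   \code{lab_id} of archival (validated) lab ids, NA = unverifiable.
#' @return List of class \code{discrepancy_summary}:
#'   \code{n_relabelled} (corrected individual and/or lab id differs),
#'   \code{n_misattributed} (corrected individual differs),
#'   \code{n_sex_contradicted} (distinct reported names whose reported sex
#'   contradicts the registry), \code{n_unresolved}.
#' @export
summarize_discrepancies <- function(assignment, reported, registry,
                                    records_lab_ids = NULL) {
  m <- merge(assignment, reported, by = "biosample",
             suffixes = c("", ".rep"))
  resolved <- !is.na(m$assigned)
  mis <- resolved & m$assigned != m$name
  lab_diff <- rep(FALSE, nrow(m))
  if (!is.null(records_lab_ids)) {
    corr <- records_lab_ids$lab_id[match(m$biosample, records_lab_ids$biosample)]
    lab_diff <- resolved & !is.na(m$lab_id) & (is.na(corr) | corr != m$lab_id)
  }
  norm_sex <- function(x) {
    c(M = "male", F = "female", male = "male", female = "female")[as.character(x)]
  }
  sex_wrong <- unique(m$name[
    m$name %in% registry$name &
    norm_sex(m$sex) != norm_sex(registry$sex[match(m$name, registry$name)])])
  structure(list(
    n_relabelled = sum(mis | lab_diff),
    n_misattributed = sum(mis),
    n_sex_contradicted = length(sex_wrong),
    n_unresolved = sum(!resolved)), class = "discrepancy_summary")
}

#' @exportS3Method base::print
print.discrepancy_summary <- function(x, ...) {
  cat(sprintf(paste0("%d sample(s) relabelled, %d attributed to the wrong ",
                     "individual, %d named individual(s) with contradicted ",
                     "sex, %d unresolved\n"),
              x$n_relabelled, x$n_misattributed, x$n_sex_contradicted,
              x$n_unresolved))
  invisible(x)
}
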