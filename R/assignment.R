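# Monte Carlo assignment of iodised-salt use. Because surveys do not
# observe which consumed products contained iodised salt, nor (in all
# survey years) who adds salt at table, salt-use status is assigned
# repeatedly by stratified sampling: within each stratum or consumer group
# an exact fraction equal to the configured proportion is drawn without
# replacement. The resulting ensemble of assignments propagates the
# assumption uncertainty into the final intake distributions.

#' Draw discretionary salt-user status for one iteration
#'
#' Within each (age band, sex) stratum of the policy's never-user table,
#' among subjects with unknown status, a fraction equal to the configured
#' never-user proportion is drawn (without replacement, exact fraction with
#' round-half-to-even) and set to non-user; the remainder are users.
#' Subjects with questionnaire-known status keep it deterministically in
#' every iteration.
#'
#' @param subjects subjects table.
#' @param policy validated salt policy.
#' @param seed root seed.
#' @param iteration iteration counter (>= 1); the draw is deterministic
#'   given `(seed, iteration)`.
#' @return named logical vector (`TRUE` = discretionary salt user), one
#'   element per subject.
#' @export
draw_discretionary <- function(subjects, policy, seed = 1L, iteration = 1L) {
  nup <- policy$never_user_proportions
  band <- band_index(nup, subjects$age, subjects$sex)
  if (anyNA(band)) {
    bad <- unique(paste0("(", subjects$age[is.na(band)], ", ",
                         subjects$sex[is.na(band)], ")"))
    fail("draw_discretionary: never_user_proportions does not cover: ",
         paste(utils::head(bad, 6), collapse = ", "))
  }
  user <- subjects$discretionary_status == "adds_salt"
  names(user) <- subjects$subject_id
  unknown <- subjects$discretionary_status == "unknown"
  with_seed(iteration_seed(seed, iteration * 2L), {
    for (bi in unique(band[unknown])) {
      in_cell <- which(unknown & band == bi)
      sel_never <- draw_exact_fraction(length(in_cell), nup$proportion[bi])
      user[in_cell] <- !sel_never
    }
  })
  user
}

#' Draw food-group salt-use flags for one iteration
#'
#' Manufacturer groups: among consumers of each group (subjects with at
#' least one record of it), a fraction equal to the group's market share is
#' assigned as consuming the iodised-salt variant. Discretionary groups:
#' among discretionary salt users consuming each eligible group, the
#' configured `use_share` fraction is assigned as adding salt to it.
#' Within an iteration a subject's products in a group are all iodised or
#' all not.
#'
#' @param subjects subjects table.
#' @param records consumption records.
#' @param policy validated salt policy.
#' @param discretionary_user named logical vector from
#'   [draw_discretionary()].
#' @param seed,iteration as in [draw_discretionary()].
#' @return list with logical matrices `iodised` (subjects x manufacturer
#'   groups) and `adds_salt` (subjects x eligible groups), rownames =
#'   subject ids.
#' @export
draw_food_group_use <- function(subjects, records, policy,
                                discretionary_user, seed = 1L,
                                iteration = 1L) {
  ids <- subjects$subject_id
  mgroups <- names(policy$manufacturer)
  dgroups <- names(policy$discretionary$added_amount)
  iodised <- matrix(FALSE, length(ids), length(mgroups),
                    dimnames = list(ids, mgroups))
  adds <- matrix(FALSE, length(ids), length(dgroups),
                 dimnames = list(ids, dgroups))
  consumers <- function(group) {
    unique(records$subject_id[records$food_group == group])
  }
  with_seed(iteration_seed(seed, iteration * 2L + 1L), {
    for (g in mgroups) {
      cons <- consumers(g)
      if (!length(cons)) next
      sel <- draw_exact_fraction(length(cons),
                                 policy$manufacturer[[g]]$market_share)
      iodised[cons[sel], g] <- TRUE
    }
    for (g in dgroups) {
      cons <- consumers(g)
      cons <- cons[discretionary_user[cons]]
      if (!length(cons)) next
      sel <- draw_exact_fraction(length(cons),
                                 policy$discretionary$use_share[[g]])
      adds[cons[sel], g] <- TRUE
    }
  })
  list(iodised = iodised, adds_salt = adds)
}

#' Build an ensemble of salt-use assignments
#'
#' Repeats [draw_discretionary()] and [draw_food_group_use()] for
#' `n_iterations` iterations. Iterations use independent sub-streams
#' derived from the root seed by a counter-based scheme, so iteration `i`
#' is reproducible in isolation from `(seed, i)`.
#'
#' @param subjects subjects table.
#' @param records consumption records.
#' @param policy validated salt policy.
#' @param n_iterations number of Monte Carlo assignment iterations (>= 1).
#' @param seed root seed.
#' @return list of assignments; each has `iteration`,
#'   `discretionary_user`, `adds_salt` and `iodised`.
#' @export
build_ensemble <- function(subjects, records, policy, n_iterations = 100L,
                           seed = 1L) {
  if (n_iterations < 1) fail("build_ensemble: n_iterations must be >= 1")
  lapply(seq_len(n_iterations), function(i) {
    du <- draw_discretionary(subjects, policy, seed, i)
    fg <- draw_food_group_use(subjects, records, policy, du, seed, i)
    list(iteration = i, discretionary_user = du,
         adds_salt = fg$adds_salt, iodised = fg$iodised)
  })
}
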