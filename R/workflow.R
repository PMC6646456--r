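# Multiuser annotation workflow: users belong to roles, roles acquire series
# from pools and assign them onward to pools or named users. A series is held
# by exactly one of {pool, owner} at all times; only the owner may edit it,
# and every ownership change commits a version automatically. The workflow is
# described in YAML:
#
#   users:
#     analyst1: analyst
#     reviewer1: reviewer
#   pools: [analyst, reviewer, scientist]
#   initial_pool: analyst
#   rights:
#     analyst:
#       may_acquire_from: [analyst]
#       may_assign_to: [analyst, reviewer]
#     reviewer:
#       may_acquire_from: [reviewer]
#       may_assign_to: [analyst, scientist]
#       may_assign_to_users: [analyst1]

#' Parse and validate a workflow description
#'
#' @param yaml_text workflow YAML as a single string, or a parsed list.
#' @return a validated `voxann_workflow` spec.
#' @export
parse_workflow <- function(yaml_text) {
  spec <- if (is.character(yaml_text)) yaml::yaml.load(yaml_text) else
    yaml_text
  users <- spec$users
  if (is.null(users) || !length(users))
    va_stop("validation", "workflow must declare at least one user")
  pools <- unlist(spec$pools)
  if (!length(pools)) va_stop("validation", "workflow declares no pools")
  if (is.null(spec$initial_pool))
    va_stop("validation", "workflow must declare initial_pool")
  if (!spec$initial_pool %in% pools)
    va_stop("validation", "initial_pool '", spec$initial_pool,
            "' is not a declared pool")
  roles <- unique(unlist(users))
  rights <- spec$rights %||% list()
  for (role in names(rights)) {
    r <- rights[[role]]
    bad <- setdiff(unlist(r$may_acquire_from), pools)
    if (length(bad))
      va_stop("validation", "right for role '", role,
              "' references undeclared pool(s): ",
              paste(bad, collapse = ", "))
    bad <- setdiff(unlist(r$may_assign_to), pools)
    if (length(bad))
      va_stop("validation", "right for role '", role,
              "' references undeclared pool(s): ",
              paste(bad, collapse = ", "))
    bad <- setdiff(unlist(r$may_assign_to_users), names(users))
    if (length(bad))
      va_stop("validation", "right for role '", role,
              "' references undeclared user(s): ",
              paste(bad, collapse = ", "))
  }
  structure(list(users = users, pools = pools, roles = roles,
                 rights = rights, initial_pool = spec$initial_pool),
            class = "voxann_workflow")
}

#' Attach a workflow to a project
#'
#' Every already-registered unowned series is placed in the initial pool.
#'
#' @inheritParams define_roi
#' @param workflow a `voxann_workflow` from [parse_workflow()], or YAML text.
#' @export
set_workflow <- function(project, workflow) {
  if (!inherits(workflow, "voxann_workflow"))
    workflow <- parse_workflow(workflow)
  project$workflow <- workflow
  for (sid in names(project$custody)) {
    c <- project$custody[[sid]]
    if (is.null(c$owner) && is.null(c$pool)) {
      c$pool <- workflow$initial_pool
      project$custody[[sid]] <- c
    }
  }
  invisible(workflow)
}

user_role <- function(wf, user) {
  role <- wf$users[[user %||% ""]]
  if (is.null(role)) va_stop("lookup", "unknown user: '", user %||% "<none>",
                             "'")
  role
}

custody_of <- function(project, series) {
  series_get(project, series)
  project$custody[[series]]
}

#' Acquire a series from a pool
#'
#' The acting user's role must hold the `may_acquire_from` right for the pool
#' the series currently waits in, and the series must not be owned.
#' Acquisition locks the series to other users: only the owner can edit it.
#'
#' @inheritParams apply_edit
#' @param user acquiring user id.
#' @return the updated custody record, invisibly.
#' @export
acquire <- function(project, series, user) {
  wf <- project$workflow
  if (is.null(wf)) va_stop("precondition", "project has no workflow")
  role <- user_role(wf, user)
  cust <- custody_of(project, series)
  if (!is.null(cust$owner))
    va_stop("contention", "series '", series, "' is already owned by '",
            cust$owner, "'")
  allowed <- unlist(wf$rights[[role]]$may_acquire_from)
  if (!(cust$pool %in% allowed))
    va_stop("permission", "role '", role, "' may not acquire from pool '",
            cust$pool, "'")
  cust$owner <- user
  cust$pool <- NULL
  cust$locked <- TRUE
  project$custody[[series]] <- cust
  invisible(cust)
}

#' Release a series to a pool or assign it to a user
#'
#' Only the current owner can release. The target must fall within the
#' owner's `may_assign_to` (pools) or `may_assign_to_users` rights, or be the
#' pool the user may acquire from (returning work). Every ownership change
#' automatically commits a version of the series' annotations.
#'
#' @inheritParams acquire
#' @param target a pool name or a user id.
#' @return the updated custody record, invisibly.
#' @export
release <- function(project, series, user, target) {
  wf <- project$workflow
  if (is.null(wf)) va_stop("precondition", "project has no workflow")
  role <- user_role(wf, user)
  cust <- custody_of(project, series)
  if (!identical(cust$owner, user))
    va_stop("permission", "user '", user, "' does not own series '",
            series, "'")
  r <- wf$rights[[role]]
  to_pool <- target %in% unlist(c(r$may_assign_to, r$may_acquire_from))
  to_user <- target %in% unlist(r$may_assign_to_users)
  if (target %in% wf$pools && !to_pool)
    va_stop("permission", "role '", role, "' may not assign to pool '",
            target, "'")
  if (!(target %in% wf$pools) && !to_user)
    va_stop("permission", "role '", role, "' may not assign to '", target,
            "'")
  commit_version(project, series, user, note = "ownership change")
  if (target %in% wf$pools) {
    cust$owner <- NULL; cust$pool <- target; cust$locked <- FALSE
  } else {
    cust$owner <- target; cust$pool <- NULL; cust$locked <- TRUE
  }
  project$custody[[series]] <- cust
  invisible(cust)
}

#' Can a user edit a series?
#'
#' True iff the user currently owns the series. Consulted by every mutating
#' editing verb when the project carries a workflow.
#'
#' @inheritParams acquire
#' @return logical.
#' @export
can_edit <- function(project, user, series) {
  cust <- custody_of(project, series)
  !is.null(cust$owner) && identical(cust$owner, user)
}

#' Workflow custody status of all series
#'
#' @inheritParams define_roi
#' @return data frame of series_id, holder (pool or user), owned flag.
#' @export
workflow_status <- function(project) {
  ids <- names(project$custody)
  data.frame(
    series_id = ids %||% character(),
    holder = vapply(project$custody, function(c)
      c$owner %||% c$pool %||% "<none>", "", USE.NAMES = FALSE),
    owned = vapply(project$custody, function(c) !is.null(c$owner),
                   logical(1), USE.NAMES = FALSE),
    row.names = NULL
  )
}
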