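# keep only the given label ids (others -> 0), preserving id values
.restrictLabels <- function(l, ids) {
  out <- l
  keep <- logical(nLabels(l) + 1L)
  keep[ids + 1L] <- TRUE
  keep[1L] <- FALSE
  out@.Data <- array(ifelse(keep[l@.Data + 1L], l@.Data, 0L), dim(l@.Data))
  out
}

.requireChannels <- function(kind, channels, needed) {
  missing <- setdiff(needed, names(channels))
  if (length(missing))
    stop(sprintf("workflow %d requires channels {%s}; missing: %s", kind,
                 paste(needed, collapse = ", "),
                 paste(missing, collapse = ", ")), call. = FALSE)
}

# attach assignment info to a site table
.mergeAssignment <- function(sites, assign, maskId = 1L) {
  sites$overlap_fraction <- assign$overlap_fraction[match(sites$id, assign$id)]
  sites$assigned_mask_id <- ifelse(
    assign$assigned[match(sites$id, assign$id)], maskId, NA_integer_)
  sites
}

#' Run a connectivity analysis workflow
#'
#' The four standard analysis workflows:
#' \describe{
#'   \item{1}{sites of one marker assigned to neuron 1 (detect, then assign
#'     at the 50\% colocalization rule). Channels: `marker`, `neuron1_mask`.}
#'   \item{2}{presynaptic sites assigned to neuron 1, then connections as
#'     postsynaptic sites (specific to neuron 2, Drep2-style labeling)
#'     contacting the assigned presynaptic sites at the 0.1\% rule; stage 4
#'     counts the distinct presynaptic sites participating in at least one
#'     connection. Channels: `presyn`, `neuron1_mask`, `postsyn`.}
#'   \item{3}{presynaptic sites assigned to neuron 1, then connections as
#'     those sites contacting the neuron-2 mask at the 0.1\% rule.
#'     Channels: `presyn`, `neuron1_mask`, `neuron2_mask`.}
#'   \item{4}{all sites in the volume (detect only). Channels: `marker`.}
#' }
#'
#' Mask channels may be given as [BinaryMask-class] objects; marker
#' channels as [VoxelVolume-class] objects.
#'
#' @param kind workflow number, 1-4.
#' @param channels named list of channel volumes (see above).
#' @param cfg a [PipelineConfig-class].
#' @param provider [probabilityProvider()] used to classify marker voxels.
#' @param markerRole role profile for workflows 1 and 4 (default
#'   presynaptic).
#' @return a [WorkflowReport-class]; its `summary` always carries
#'   `presyn_total` and, where the workflow defines them,
#'   `presyn_on_neuron1`, `connections` and `presyn_sites_connected`.
#' @export
runWorkflow <- function(kind, channels, cfg = pipelineConfig(),
                        provider = probabilityProvider("scaled_intensity"),
                        markerRole = "presynaptic") {
  .runWorkflowImpl(as.integer(kind), channels, cfg, provider, markerRole,
                   detector = function(v, prof) detectSites(v, provider, prof))
}

# workflow stage logic with a pluggable detection backend (global or
# blockwise); `detector(volume, profile)` must return detectSites() output
.runWorkflowImpl <- function(kind, channels, cfg, provider, markerRole,
                             detector) {
  if (!kind %in% 1:4) stop("workflow kind must be 1, 2, 3 or 4", call. = FALSE)
  sites <- list()
  labels <- list()
  connections <- .emptyConnections()
  summary <- list()

  if (kind == 1L) {
    .requireChannels(kind, channels, c("marker", "neuron1_mask"))
    det <- detector(channels$marker,
                       .profileForRole(cfg, markerRole))
    assign <- assignSitesToMask(det$labels, channels$neuron1_mask,
                                cfg@assignmentFraction)
    sites$marker <- .mergeAssignment(det$sites, assign)
    labels$marker <- det$labels
    labels$marker_assigned <- .restrictLabels(det$labels,
                                              assign$id[assign$assigned])
    summary <- list(presyn_total = nrow(det$sites),
                    presyn_on_neuron1 = sum(assign$assigned))
  } else if (kind == 2L) {
    .requireChannels(kind, channels, c("presyn", "neuron1_mask", "postsyn"))
    detPre <- detector(channels$presyn, cfg@presynProfile)
    detPost <- detector(channels$postsyn, cfg@postsynProfile)
    assign <- assignSitesToMask(detPre$labels, channels$neuron1_mask,
                                cfg@assignmentFraction)
    preAssigned <- .restrictLabels(detPre$labels, assign$id[assign$assigned])
    connections <- findSiteSiteContacts(preAssigned, detPost$labels, cfg)
    sites$presyn <- .mergeAssignment(detPre$sites, assign)
    sites$postsyn <- detPost$sites
    labels$presyn <- detPre$labels
    labels$presyn_assigned <- preAssigned
    labels$postsyn <- detPost$labels
    summary <- list(presyn_total = nrow(detPre$sites),
                    presyn_on_neuron1 = sum(assign$assigned),
                    connections = nrow(connections),
                    presyn_sites_connected =
                      length(unique(connections$pre_site_id)))
  } else if (kind == 3L) {
    .requireChannels(kind, channels, c("presyn", "neuron1_mask",
                                       "neuron2_mask"))
    detPre <- detector(channels$presyn, cfg@presynProfile)
    assign <- assignSitesToMask(detPre$labels, channels$neuron1_mask,
                                cfg@assignmentFraction)
    preAssigned <- .restrictLabels(detPre$labels, assign$id[assign$assigned])
    connections <- findSiteMaskContacts(preAssigned, channels$neuron2_mask,
                                        cfg)
    sites$presyn <- .mergeAssignment(detPre$sites, assign)
    labels$presyn <- detPre$labels
    labels$presyn_assigned <- preAssigned
    summary <- list(presyn_total = nrow(detPre$sites),
                    presyn_on_neuron1 = sum(assign$assigned),
                    connections = nrow(connections),
                    presyn_sites_connected =
                      length(unique(connections$pre_site_id)))
  } else {
    .requireChannels(kind, channels, "marker")
    det <- detector(channels$marker,
                       .profileForRole(cfg, markerRole))
    sites$marker <- det$sites
    labels$marker <- det$labels
    summary <- list(presyn_total = nrow(det$sites))
  }
  # distinct presynaptic sites in >=1 connection can never exceed the
  # number of connections (equality iff no polyadic contacts)
  if (!is.null(summary$presyn_sites_connected))
    stopifnot(summary$presyn_sites_connected <= summary$connections)
  new("WorkflowReport", kind = kind, summary = summary, sites = sites,
      connections = connections, labels = labels, config = cfg)
}

.profileForRole <- function(cfg, role) {
  switch(role,
         presynaptic = cfg@presynProfile,
         postsynaptic = cfg@postsynProfile,
         gap_junction = cfg@gapJunctionProfile,
         stop("unknown marker role: ", role, call. = FALSE))
}

#' @rdname workflowSummary
#' @export
setGeneric("workflowSummary", function(x) standardGeneric("workflowSummary"))

#' Workflow summary counts
#'
#' @param x a [WorkflowReport-class].
#' @return named list of summary counts.
#' @export
setMethod("workflowSummary", "WorkflowReport", function(x) x@summary)

#' @rdname connectionTable
#' @export
setGeneric("connectionTable", function(x) standardGeneric("connectionTable"))

#' Connection table accessor
#'
#' @param x a [WorkflowReport-class].
#' @return the connection data frame.
#' @export
setMethod("connectionTable", "WorkflowReport", function(x) x@connections)

#' @rdname siteTables
#' @export
setGeneric("siteTables", function(x) standardGeneric("siteTables"))

#' Per-stage site tables
#'
#' @param x a [WorkflowReport-class].
#' @return named list of site data frames.
#' @export
setMethod("siteTables", "WorkflowReport", function(x) x@sites)

setMethod("show", "WorkflowReport", function(object) {
  cat("WorkflowReport (workflow", object@kind, ")\n")
  s <- object@summary
  for (nm in names(s)) cat(sprintf("  %s: %s\n", nm, s[[nm]]))
})

#' Write all artifacts of a workflow run
#'
#' Emits stage CSVs (fixed schema), stage label volumes and a summary JSON
#' (`summary.json`, carrying the counts and the effective parameters) into
#' `dir`.  Re-running with identical inputs and config yields byte-identical
#' CSV/JSON outputs.
#'
#' @param report a [WorkflowReport-class].
#' @param dir output directory.
#' @param writeVolumes also export stage label volumes as chunked stores
#'   (default TRUE).
#' @return invisibly the summary list.
#' @export
writeWorkflowReport <- function(report, dir, writeVolumes = TRUE) {
  stopifnot(is(report, "WorkflowReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report@sites))
    writeSiteReport(report@sites[[nm]],
                    file.path(dir, paste0("sites_", nm, ".csv")), stage = nm)
  writeSiteReport(report@connections, file.path(dir, "connections.csv"))
  if (writeVolumes)
    for (nm in names(report@labels))
      writeVolume(report@labels[[nm]], file.path(dir, paste0("labels_", nm)),
                  format = "chunked_store")
  cfg <- report@config
  summary <- c(report@summary, list(parameters = list(
    assignment_fraction = cfg@assignmentFraction,
    contact_fraction = cfg@contactFraction,
    contact_dilation = cfg@contactDilation,
    presyn_min_size = cfg@presynProfile@minSizeVoxels,
    postsyn_min_size = cfg@postsynProfile@minSizeVoxels,
    prob_threshold = cfg@presynProfile@probThreshold,
    mask_min_size = cfg@maskMinSize,
    max_gap = cfg@bridge@maxGap,
    bridge_iterations = cfg@bridge@iterations,
    block_edge = cfg@blockEdge,
    halo = cfg@halo,
    connectivity = cfg@connectivity)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
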