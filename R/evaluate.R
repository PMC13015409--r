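#' Score a pipeline run against the synthetic ground-truth manifest
#'
#' Computes precision and recall (or exact-match indicators) for every
#' scorable layer: loop diff labels, super-enhancer calls per condition,
#' enhancer states and switches, compartment shift labels, eRNA
#' retention, variant-to-gene assignments by loop and SE mechanisms,
#' closest genes, peri-SNP counts, LD expansion, cross-tissue loop
#' sharing and SE tissue specificity.
#'
#' @param res a [run_pipeline()] result.
#' @param manifest the manifest returned by [generate_dataset()].
#' @return named list of metrics, each a list with `precision`, `recall`
#'   (or `accuracy`) and `n`.
#' @export
evaluate_against_truth <- function(res, manifest) {
  pr <- function(pred, truth) {
    pred <- unique(pred); truth <- unique(truth)
    list(precision = if (length(pred)) mean(pred %in% truth) else 1,
         recall = if (length(truth)) mean(truth %in% pred) else 1,
         n = length(truth))
  }
  out <- list()

  # loop diff labels on planted ids (decoy loops are expected stable)
  ml <- manifest$loops
  truth_label <- c(stats::setNames(ml$label, ml$loop_id),
                   if (!is.null(manifest$decoy_loops))
                     stats::setNames(rep("stable", nrow(manifest$decoy_loops)),
                                     manifest$decoy_loops$loop_id))
  split_ids <- function(x) unlist(strsplit(x, ";", fixed = TRUE))
  pred_label <- c(
    stats::setNames(rep("stable", length(split_ids(res$loop_diff$stable$name))),
                    split_ids(res$loop_diff$stable$name)),
    stats::setNames(rep("gained", length(split_ids(res$loop_diff$gained$name))),
                    split_ids(res$loop_diff$gained$name)),
    stats::setNames(rep("lost", length(split_ids(res$loop_diff$lost$name))),
                    split_ids(res$loop_diff$lost$name)))
  pred_label <- pred_label[!duplicated(names(pred_label))]
  for (lab in c("stable", "gained", "lost"))
    out[[paste0("loop_", lab)]] <- pr(
      names(pred_label)[pred_label == lab & !grepl("^noise", names(pred_label))],
      names(truth_label)[truth_label == lab])

  # super-enhancer calls per condition, by >=1 bp overlap matching
  for (cond in c("control", "dex")) {
    truth_se <- manifest[[paste0("se_", cond)]]
    called <- res$se_consensus[[cond]]
    out[[paste0("se_", cond)]] <- list(
      precision = if (nrow(called)) mean(overlaps_any(called, truth_se)) else 1,
      recall = if (nrow(truth_se)) mean(overlaps_any(truth_se, called)) else 1,
      n = nrow(truth_se))
  }

  # enhancer states and switches on manifest elements (exact intervals)
  te <- manifest$enhancers
  pe <- res$enhancers
  key <- function(d) paste(d$chrom, d$start, d$end)
  m <- match(key(te), key(pe))
  matched <- !is.na(m)
  states_ok <- matched &
    te$state_control == pe$state_control[m] &
    te$state_treated == pe$state_treated[m]
  out$enhancer_states <- list(precision = mean(states_ok[matched]),
                              recall = mean(matched), n = nrow(te))
  out$enhancer_switch <- pr(
    key(te)[matched][pe$switch[m[matched]] %in% c("activated", "deactivated")],
    key(te)[te$switch %in% c("activated", "deactivated")])
  out$switch_fraction <- list(
    planted = mean(te$switch %in% c("activated", "deactivated")),
    recovered = if (any(matched))
      mean(pe$switch[m[matched]] %in% c("activated", "deactivated")) else NA,
    n = nrow(te))

  # compartment shifts: exact window-key sets per direction
  tw <- manifest$compartment_windows
  sw <- res$compartment_shifts
  for (dir in c("toward_A", "toward_B"))
    out[[paste0("compartment_", dir)]] <- pr(
      paste(sw$chrom, sw$start)[sw$shift == dir],
      paste(tw$chrom, tw$start)[tw$shift == dir])

  # eRNA retention
  out$erna <- pr(res$ernas$id[res$ernas$expressed],
                 manifest$erna$expressed_ids)

  # variant-to-gene, loop and SE mechanisms (leads; resource loop set)
  v2g <- manifest$v2g
  lt <- res$loop_targets
  lt <- lt[lt$loop_set == "resource", , drop = FALSE]
  out$v2g_loop <- pr(paste(lt$rsid, lt$gene_id),
                     paste(v2g$rsid, v2g$gene_id)[v2g$mechanism == "loop"])
  st <- res$se_targets
  out$v2g_se <- pr(paste(st$rsid, st$gene_id),
                   paste(v2g$rsid, v2g$gene_id)[v2g$mechanism == "super_enhancer"])

  # closest genes on the dedicated leads
  ct <- manifest$closest
  cg <- res$closest_genes
  cg <- cg[cg$rsid %in% ct$rsid, , drop = FALSE]
  out$closest <- pr(paste(cg$rsid, cg$gene_id, cg$distance),
                    paste(ct$rsid, ct$gene_id, ct$distance))

  # peri-SNP counts on the dedicated leads
  pt <- manifest$peri_snp
  pp <- res$peri_snp
  mm <- merge(pt, pp, by = c("rsid", "mark"))
  out$peri_snp <- list(
    accuracy = if (nrow(mm)) mean(mm$n_gained.x == mm$n_gained.y &
                                    mm$n_lost.x == mm$n_lost.y) else NA,
    recall = nrow(mm) / nrow(pt), n = nrow(pt))

  # SNP-compartment labels on the dedicated leads
  sct <- manifest$snp_compartment
  scp <- res$snp_compartments
  msc <- merge(sct, scp, by = "rsid")
  out$snp_compartment <- list(
    accuracy = if (nrow(msc)) mean(msc$shift.x == msc$shift.y) else NA,
    recall = nrow(msc) / nrow(sct), n = nrow(sct))

  # LD expansion
  retained <- res$ld_variants$rsid[!res$ld_variants$is_lead]
  out$ld <- pr(retained, manifest$ld$expected_retained)

  # cross-tissue sharing
  if (!is.null(res$tissue_sharing)) {
    ts <- res$tissue_sharing
    ids <- lapply(strsplit(ts$loop_id, ";", fixed = TRUE), identity)
    first_id <- vapply(ids, `[`, character(1), 1)
    shared_pred <- first_id[ts$n_tissues == manifest$tissue_sharing$n_tissues]
    zero_pred <- first_id[ts$n_tissues == 0]
    out$tissue_shared <- pr(intersect(shared_pred, manifest$loops$loop_id),
                            manifest$tissue_sharing$shared_ids)
    out$tissue_specific <- list(
      recall = mean(manifest$tissue_sharing$specific_ids %in% zero_pred),
      n = length(manifest$tissue_sharing$specific_ids))
  }

  # SE tissue specificity fractions
  if (!is.null(res$se_specificity)) {
    sp <- res$se_specificity
    truth_se <- manifest$se_control
    hit <- overlap_pairs(sp[, c("chrom", "start", "end")], truth_se)
    if (nrow(hit)) {
      spec <- truth_se$specificity[hit$subject]
      frac <- sp$fraction_samples[hit$query]
      out$se_specificity <- list(
        specific_ok = mean(frac[spec == "tm_specific"] < 0.05),
        ubiquitous_ok = mean(frac[spec == "ubiquitous"] > 0.9),
        n = nrow(truth_se))
    }
  }
  out
}
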