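# Fixture ROESY tables reconstructed from the printed per-system summary
# values (homo baselines, which hetero peaks lie above them); the
# individual hetero volumes not printed anywhere are synthetic but chosen
# to respect every stated ordering.

roesy_sites <- function(agent_ids, aromatic) {
  data.frame(id = c("A", "B", "C", "D", agent_ids),
             molecule = c(rep("xanthine", 4L), rep("agent", length(agent_ids))),
             aromatic = c(TRUE, TRUE, FALSE, FALSE, aromatic),
             stringsAsFactors = FALSE)
}

# cholinium caffeate system: weakest homo peaks of all systems
# ([B-C] = 0.09, [B-D] = 0.05), ring-proton hetero peaks stronger
roesy_caffeate <- function() {
  peaks <- data.frame(
    site_a = c("A", "B", "B", "B", "C", "D", "B", "C"),
    site_b = c("B", "C", "D", "2", "2", "3", "4", "4"),
    volume = c(1.00, 0.09, 0.05, 0.35, 0.28, 0.30, 0.12, 0.10))
  roesy_table(peaks, roesy_sites(c("2", "3", "4"), c(TRUE, TRUE, FALSE)),
              m_xanthine = 2.5, m_agent = 3.2, system = "caffeate")
}

# cholinium ferulate: same regime as caffeate
roesy_ferulate <- function() {
  peaks <- data.frame(
    site_a = c("A", "B", "B", "B", "C", "D", "B"),
    site_b = c("B", "C", "D", "2", "2", "3", "4"),
    volume = c(1.00, 0.09, 0.05, 0.40, 0.33, 0.31, 0.11))
  roesy_table(peaks, roesy_sites(c("2", "3", "4"), c(TRUE, TRUE, FALSE)),
              m_xanthine = 2.5, m_agent = 3.4, system = "ferulate")
}

# sodium salicylate: homo baseline 0.21, yet every aromatic-ring hetero
# peak is stronger still
roesy_salicylate <- function() {
  peaks <- data.frame(
    site_a = c("A", "B", "B", "B", "C", "D", "C"),
    site_b = c("B", "C", "D", "2", "2", "3", "3"),
    volume = c(1.00, 0.21, 0.21, 0.30, 0.28, 0.26, 0.25))
  roesy_table(peaks, roesy_sites(c("2", "3"), c(TRUE, TRUE)),
              m_xanthine = 3.0, m_agent = 3.0, system = "salicylate")
}

# sodium nicotinate: baseline 0.12; exactly four hetero peaks
# ([C-4], [C-5], [D-4], [D-5]) above it, the rest below; xanthine three
# times more dilute than the agent
roesy_nicotinate <- function() {
  peaks <- data.frame(
    site_a = c("A", "B", "B", "C", "C", "D", "D", "B", "B", "C", "D",
               "B", "B"),
    site_b = c("B", "C", "D", "4", "5", "4", "5", "2", "4", "2", "2",
               "5", "6"),
    volume = c(1.00, 0.12, 0.12, 0.16, 0.15, 0.14, 0.13, 0.08, 0.07,
               0.06, 0.05, 0.04, 0.03))
  roesy_table(peaks, roesy_sites(c("2", "4", "5", "6"),
                                 c(TRUE, TRUE, TRUE, TRUE)),
              m_xanthine = 0.9, m_agent = 3.0, system = "nicotinate")
}

# niacinamide: the largest homo baseline (0.23), above every hetero peak
roesy_niacinamide <- function() {
  peaks <- data.frame(
    site_a = c("A", "B", "B", "B", "C", "D", "C"),
    site_b = c("B", "C", "D", "2", "2", "3", "3"),
    volume = c(1.00, 0.23, 0.23, 0.15, 0.12, 0.10, 0.08))
  roesy_table(peaks, roesy_sites(c("2", "3"), c(TRUE, TRUE)),
              m_xanthine = 1.5, m_agent = 3.0, system = "niacinamide")
}
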