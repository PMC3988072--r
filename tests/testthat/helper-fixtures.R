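# Shared worked-example fixtures.

# Topology stats of five canonical inflammatory hub genes (degree and
# normalized betweenness as reported by a network-analyzer run on a
# 145-node inflammation interactome).
hubStatsFixture <- function() {
    TopologyStats(
        node = c("IL6", "VEGFA", "IL1B", "TNF", "PTGS2"),
        degree = c(77L, 61L, 61L, 62L, 49L),
        betweenness = c(0.10995103, 0.09511043, 0.05885691,
                        0.05394098, 0.05242533))
}

# Hub retention frequencies per deletion level from a 97-test-network
# validation (rows: 1-4 deleted nodes; columns: IL6, IL1B, TNF, PTGS2,
# VEGFA), with the number of test networks per level.
retentionFixture <- function() {
    list(freq = rbind(`1` = c(21L, 21L, 21L, 21L, 20L),
                      `2` = c(20L, 20L, 20L, 19L, 20L),
                      `3` = c(20L, 23L, 18L, 17L, 9L),
                      `4` = c(20L, 23L, 18L, 19L, 4L)),
         n = c(22L, 25L, 25L, 25L))
}
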