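{
  "title": "hubnet pipeline summary",
  "required": {
    "seed": "integer",
    "n_seed_genes": "integer",
    "n_nodes": "integer",
    "n_edges": "integer",
    "power_law_r2": "number",
    "hubs": "string_array",
    "backbone_nodes": "integer",
    "backbone_edges": "integer",
    "hub_edge_fraction": "number",
    "n_test_networks": "integer",
    "accuracy_table": "table",
    "overall_accuracy": "number",
    "n_unique_tfs": "integer",
    "top_tfs": "string_array",
    "group_comparison": "table"
  }
}
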