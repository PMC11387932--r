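{
  "dataset": "ancientmetagenome-hostassociated",
  "table_type": "libraries",
  "key_columns": ["library_name", "archive_data_accession"],
  "columns": [
    {"name": "project_name", "value_kind": "free_text"},
    {"name": "publication_year", "value_kind": "integer", "missing_token_allowed": true},
    {"name": "data_publication_doi", "value_kind": "doi", "missing_token_allowed": true},
    {"name": "sample_name", "value_kind": "free_text"},
    {"name": "archive", "value_kind": "enum", "enum": "archive"},
    {"name": "archive_project", "value_kind": "accession_list"},
    {"name": "archive_sample_accession", "value_kind": "accession_list"},
    {"name": "library_name", "value_kind": "free_text"},
    {"name": "strand_type", "value_kind": "enum", "enum": "strand_type"},
    {"name": "library_polymerase", "value_kind": "enum", "enum": "library_polymerase"},
    {"name": "library_treatment", "value_kind": "enum", "enum": "library_treatment"},
    {"name": "instrument_model", "value_kind": "enum", "enum": "instrument_model"},
    {"name": "library_layout", "value_kind": "enum", "enum": "library_layout"},
    {"name": "library_strategy", "value_kind": "enum", "enum": "library_strategy"},
    {"name": "read_count", "value_kind": "integer", "missing_token_allowed": true},
    {"name": "archive_data_accession", "value_kind": "accession_list"},
    {"name": "download_links", "value_kind": "url_list"},
    {"name": "download_md5s", "value_kind": "md5_list"},
    {"name": "download_sizes", "value_kind": "byte_size_list"}
  ]
}
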