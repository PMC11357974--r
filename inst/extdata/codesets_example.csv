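set_name,system,code,match_mode
etoposide,HCPCS_CPT,J9181,exact
etoposide,HCPCS_CPT,J8560,exact
etoposide_ndc,NDC,00703564411,exact
etoposide_ndc,NDC,00015306120,exact
egfr_test,HCPCS_CPT,81235,exact
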