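metabolite,formula,n_tracer_carbons,note
pyruvate,C6H12NO3Si,3,MOX-TBDMS [M-57]+ curated default; verify against local method
lactate,C11H25O3Si2,3,2TBDMS [M-57]+ curated default; verify against local method
alanine,C11H26NO2Si2,3,2TBDMS [M-57]+ curated default; verify against local method
glycine,C10H24NO2Si2,2,2TBDMS [M-57]+ curated default; verify against local method
serine,C16H38NO3Si3,3,3TBDMS [M-57]+ curated default; verify against local method
aspartate,C17H36NO4Si3,4,3TBDMS [M-57]+ curated default; verify against local method
asparagine,C17H37N2O3Si3,4,3TBDMS [M-57]+ curated default; verify against local method
glutamate,C18H38NO4Si3,5,3TBDMS [M-57]+ curated default; verify against local method
glutamine,C18H39N2O3Si3,5,3TBDMS [M-57]+ curated default; verify against local method
proline,C13H28NO2Si2,5,2TBDMS [M-57]+ curated default; verify against local method
citrate,C20H39O6Si2,6,4TBDMS m/z 459 fragment curated default; verify against local method
alpha_ketoglutarate,C14H28NO5Si2,5,MOX-2TBDMS [M-57]+ curated default; verify against local method
succinate,C12H25O4Si2,4,2TBDMS [M-57]+ curated default; verify against local method
fumarate,C12H23O4Si2,4,2TBDMS [M-57]+ curated default; verify against local method
malate,C17H35O5Si3,4,3TBDMS [M-57]+ curated default; verify against local method
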