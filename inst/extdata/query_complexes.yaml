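# Deposited aspirin/salicylate protein complexes usable as binding-site
# queries. Within each family one entry is kept (keep: true wins its family,
# otherwise the first listed); the lactoperoxidase pair keeps 3GCL.
complexes:
  - struct_id: 1OXR
    ligand: AIN
    family: phospholipase A2
  - struct_id: 1TGM
    ligand: AIN
    family: phospholipase A2
  - struct_id: 2QQT
    ligand: AIN
    family: lactoperoxidase
  - struct_id: 3GCL
    ligand: AIN
    family: lactoperoxidase
    keep: true
  - struct_id: 4NSB
    ligand: AIN
    family: chitinase-3-like protein 1
  - struct_id: 3IAZ
    ligand: AIN
    family: lactotransferrin
  - struct_id: 1PTH
    ligand: SAL
    family: cyclooxygenase-1
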