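name,species,lambda_um,a_um,N,evidence_class,provenance_note
Wg,Drosophila,3.5,1.3,25,DT,synthetic placeholder values - unverified
Hh,Drosophila,4.0,1.3,25,DT,synthetic placeholder values - unverified
Dpp,Drosophila,20.0,1.3,30,multiple,synthetic placeholder values - unverified
Bicoid,Drosophila,100.0,8.5,30,SDC,synthetic placeholder values - unverified
Dorsal,Drosophila,70.0,8.5,30,multiple,synthetic placeholder values - unverified
Fgf8,zebrafish,75.0,5.0,40,SDC,synthetic placeholder values - unverified
Cyclops,zebrafish,12.0,5.0,40,multiple,synthetic placeholder values - unverified
Squint,zebrafish,15.0,5.0,40,multiple,synthetic placeholder values - unverified
Lefty1,zebrafish,60.0,5.0,40,SDC,synthetic placeholder values - unverified
Lefty2,zebrafish,70.0,5.0,40,SDC,synthetic placeholder values - unverified
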