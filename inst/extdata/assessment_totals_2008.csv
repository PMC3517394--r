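quantity,count
parcels_in_study_area,17242
excluded_unsafe_or_not_visible,598
residential,13398
commercial,681
unoccupied_or_demolished_lot,1253
religious_institution,153
community_property,225
residential_apartment,505
residential_single_family,11182
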