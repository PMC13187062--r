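specimen_id,length_mm,bone_type,condition,structure
FK-B-001,7,Compact bone,not_good,osteon_uncertain
FK-B-002,7,Compact bone,good,osteon
FK-B-003,8,Compact bone,good,osteon
FK-B-004,5,Compact bone,not_good,osteon_uncertain
FK-B-005,4,Compact bone,not_good,osteon_uncertain
FK-B-006,8,Compact bone,good,osteon
FK-B-007,2,Compact bone,good,plexiform
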