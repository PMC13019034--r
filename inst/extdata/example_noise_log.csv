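location_id,start,end,leq_db
ward_internal,07:00,10:00,61.2
ward_internal,10:00,13:00,62.8
ward_internal,13:00,16:00,60.4
ward_internal,16:00,19:00,59.1
ward_internal,19:00,22:00,56.3
ward_internal,22:00,01:00,52.7
ward_internal,01:00,04:00,49.8
ward_internal,04:00,07:00,51.5
ward_ccu,07:00,10:00,58.9
ward_ccu,10:00,13:00,59.6
ward_ccu,13:00,16:00,58.2
ward_ccu,16:00,19:00,57.4
ward_ccu,19:00,22:00,55.0
ward_ccu,22:00,01:00,51.9
ward_ccu,01:00,04:00,48.3
ward_ccu,04:00,07:00,50.1
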