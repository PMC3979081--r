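record_type,patient_id,exam_time_years,reader_id,dvu,endplate,region,slice_domain,size_grade,cortex_large,midpoint_large
lesion,example,0,r1,T11/T12,caudal,anterior_corner,central,present_small,,
lesion,example,0,r1,T12/L1,caudal,anterior_corner,central,present_small,,
lesion,example,0,r1,L1/L2,caudal,anterior_corner,central,present_small,,
lesion,example,0,r1,L2/L3,caudal,anterior_corner,central,present_small,,
lesion,example,0,r1,L2/L3,cranial,anterior_corner,central,present_large,,
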