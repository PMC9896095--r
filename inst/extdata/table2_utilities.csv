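group,follow_up,category,count,mean_utility
control,3,physiotherapy,13,0.651
control,3,orthopaedics,20,0.719
control,3,surgery,5,0.713
index,3,specialised_MT,40,0.737
control,6,physiotherapy,14,0.650
control,6,orthopaedics,2,0.796
control,6,recovered_no_treatment,13,0.791
control,6,not_recovered_no_treatment,9,0.728
index,6,orthopaedics,10,0.699
index,6,surgery,1,0.537
index,6,recovered_no_treatment,24,0.804
index,6,not_recovered_no_treatment,5,0.616
control,12,physiotherapy,10,0.643
control,12,orthopaedics,1,0.595
control,12,surgery,2,0.678
control,12,recovered_no_treatment,12,0.842
control,12,not_recovered_no_treatment,12,0.681
index,12,physiotherapy,2,0.606
index,12,recovered_no_treatment,29,0.812
index,12,not_recovered_no_treatment,7,0.586
control,96,physiotherapy,10,0.690
control,96,surgery,2,0.568
control,96,recovered_no_treatment,20,0.763
control,96,not_recovered_no_treatment,5,0.615
index,96,specialised_MT,2,0.808
index,96,physiotherapy,1,0.887
index,96,surgery,5,0.785
index,96,recovered_no_treatment,26,0.853
index,96,not_recovered_no_treatment,4,0.649
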