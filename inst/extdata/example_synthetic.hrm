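[Params]
Version=106
Monitor=22
SMode=11111110
Date=20260101
StartTime=08:00:00.0
Length=00:00:16.2
Interval=238

[HRData]
802
815
798
824
810
791
806
833
819
801
788
812
827
805
796
818
809
797
821
808
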