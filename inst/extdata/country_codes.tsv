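name	code
UNITED STATES	US
USA	US
UNITED STATES OF AMERICA	US
UNITED KINGDOM	GB
GREAT BRITAIN	GB
JAPAN	JP
FRANCE	FR
GERMANY	DE
CANADA	CA
ITALY	IT
SPAIN	ES
BRAZIL	BR
AUSTRALIA	AU
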